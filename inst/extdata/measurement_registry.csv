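code,bone,label,region,bilateral
V1,CLAVICLE,Max. length,shoulder girdle,TRUE
V2,CLAVICLE,Sagittal diameter MS,shoulder girdle,TRUE
V3,CLAVICLE,Vertical diameter MS,shoulder girdle,TRUE
V4,SCAPULA,Height,shoulder girdle,TRUE
V5,SCAPULA,Medio-lateral breadth,shoulder girdle,TRUE
V6,SCAPULA,Glen. cavity height,shoulder girdle,TRUE
V7,SCAPULA,Glen. cavity breadth,shoulder girdle,TRUE
V8,HUMERUS,Epicondylar breadth,upper limb,TRUE
V9,HUMERUS,Max. head diameter,upper limb,TRUE
V10,HUMERUS,Sagittal diameter MS,upper limb,TRUE
V11,HUMERUS,Transverse diameter MS,upper limb,TRUE
V12,HUMERUS,Max. length,upper limb,TRUE
V13,ULNA,Max. length,upper limb,TRUE
V14,ULNA,Physiological length,upper limb,TRUE
V15,ULNA,Min. circumference,upper limb,TRUE
V16,ULNA,Max. diameter MS,upper limb,TRUE
V17,ULNA,Min. diameter MS,upper limb,TRUE
V18,ULNA,Trochlear notch breadth,upper limb,TRUE
V19,RADIUS,Max. length,upper limb,TRUE
V20,RADIUS,Sag. diameter MS,upper limb,TRUE
V21,RADIUS,Trans. diameter MS,upper limb,TRUE
V22,RADIUS,Max. head diameter,upper limb,TRUE
V23,SCAPHOID,Max. length,hand,TRUE
V24,SCAPHOID,Max. width,hand,TRUE
V25,LUNATE,Length,hand,TRUE
V26,LUNATE,Width,hand,TRUE
V27,TRIQUETRAL,Max width,hand,TRUE
V28,TRIQUETRAL,Max height,hand,TRUE
V29,PISIFORM,Max. length,hand,TRUE
V30,PISIFORM,Max. width,hand,TRUE
V31,TRAPEZIUM,Max. length,hand,TRUE
V32,TRAPEZIUM,Height,hand,TRUE
V33,TRAPEZOID,Length of palmar surf.,hand,TRUE
V34,TRAPEZOID,Width of dorsal surf.,hand,TRUE
V35,CAPITATE,Height,hand,TRUE
V36,CAPITATE,Width of distal base,hand,TRUE
V37,HAMATE,Max. height,hand,TRUE
V38,HAMATE,Max. width,hand,TRUE
V39,MC1,Max. length,hand,TRUE
V40,MC2,Max. length,hand,TRUE
V41,MC3,Max. length,hand,TRUE
V42,MC4,Max. length,hand,TRUE
V43,MC5,Max. length,hand,TRUE
V44,STERNUM,Manubrium length,thorax,FALSE
V45,STERNUM,Body length,thorax,FALSE
V46,STERNUM,Total length,thorax,FALSE
V47,STERNUM,Manubrium max. width,thorax,FALSE
V48,STERNUM,Sup. body width,thorax,FALSE
V49,STERNUM,Inf. Body width,thorax,FALSE
V50,RIB1,Max. chord,thorax,TRUE
V51,RIB1,Min. chord,thorax,TRUE
V52,RIB4,Width,thorax,TRUE
V53,ATLAS,Sagittal diameter,vertebral column,FALSE
V54,ATLAS,Transverse diameter,vertebral column,FALSE
V55,C2,Max. sagittal length,vertebral column,FALSE
V56,C2,Max. height,vertebral column,FALSE
V57,C2,Max. breadth sup. facets,vertebral column,FALSE
V58,C7,Ant. body height,vertebral column,FALSE
V59,C7,Sag. length,vertebral column,FALSE
V60,C7,Max width,vertebral column,FALSE
V61,T1,Ant. body height,vertebral column,FALSE
V62,T1,Sag. length,vertebral column,FALSE
V63,T1,Width at costal head facets,vertebral column,FALSE
V64,T12,Ant. body height,vertebral column,FALSE
V65,T12,Sag. length,vertebral column,FALSE
V66,T12,Width at costal head facets,vertebral column,FALSE
V67,L1,Ant. body height,vertebral column,FALSE
V68,L1,Sag. length,vertebral column,FALSE
V69,L1,Max. endplate width,vertebral column,FALSE
V70,L5,Ant. body height,vertebral column,FALSE
V71,L5,Sag. length,vertebral column,FALSE
V72,L5,Max. endplate width,vertebral column,FALSE
V73,OS COXAE,Max. heigth,pelvic girdle,TRUE
V74,OS COXAE,Min. ischium length,pelvic girdle,TRUE
V75,OS COXAE,Iliac breadth,pelvic girdle,TRUE
V76,OS COXAE,Min. pubis length,pelvic girdle,TRUE
V77,OS COXAE,Max. I.P. ramus length,pelvic girdle,TRUE
V78,SACRUM,S1 trans. diameter,pelvic girdle,FALSE
V79,SACRUM,S1 sagittal diameter,pelvic girdle,FALSE
V80,SACRUM,Anterior height,pelvic girdle,FALSE
V81,SACRUM,Anterior breadth,pelvic girdle,FALSE
V82,FEMUR,Epicondylar breadth,lower limb,TRUE
V83,FEMUR,Max. head diameter,lower limb,TRUE
V84,FEMUR,Circumference MS,lower limb,TRUE
V85,FEMUR,Trans. Diameter MS,lower limb,TRUE
V86,FEMUR,Sagittal diameter MS,lower limb,TRUE
V87,FEMUR,Trans. subtroch. diameter,lower limb,TRUE
V88,FEMUR,Bicondylar length,lower limb,TRUE
V89,FEMUR,Max. length,lower limb,TRUE
V90,FEMUR,Med. cond. max. length,lower limb,TRUE
V91,FEMUR,Lat. cond. max. length,lower limb,TRUE
V92,TIBIA,Prox. epiphyseal breadth,lower limb,TRUE
V93,TIBIA,Dist. epiphyseal breadth,lower limb,TRUE
V94,TIBIA,Nut. for. circumference,lower limb,TRUE
V95,TIBIA,Nut. for. trans. diameter,lower limb,TRUE
V96,TIBIA,Nut. for. AP diameter,lower limb,TRUE
V97,TIBIA,Length,lower limb,TRUE
V98,FIBULA,Max. diameter MS,lower limb,TRUE
V99,FIBULA,Max. length,lower limb,TRUE
V100,CALCANEUS,Max. length,foot,TRUE
V101,CALCANEUS,Middle breadth,foot,TRUE
V102,TALUS,Length,foot,TRUE
V103,TALUS,Breadth,foot,TRUE
V104,CUBOID,Length,foot,TRUE
V105,CUBOID,Breadth,foot,TRUE
V106,NAVICULAR,Length,foot,TRUE
V107,NAVICULAR,Breadth,foot,TRUE
V108,MED CUNEIFORM,Length,foot,TRUE
V109,MED CUNEIFORM,Height,foot,TRUE
V110,INT CUNEIFORM,Length,foot,TRUE
V111,INT CUNEIFORM,Height,foot,TRUE
V112,LAT CUNEIFORM,Length,foot,TRUE
V113,LAT CUNEIFORM,Height,foot,TRUE
V114,MT1,Max. length,foot,TRUE
V115,MT2,Max. length,foot,TRUE
V116,MT3,Max. length,foot,TRUE
V117,MT4,Max. length,foot,TRUE
V118,MT5,Max. length,foot,TRUE
V119,PATELLA,Max. length,lower limb,TRUE
V120,PATELLA,Max. breadth,lower limb,TRUE
V121,PATELLA,Max. thickness,lower limb,TRUE
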