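#' Postcranial measurement registry
#'
#' Returns the registry of the 121 standard postcranial measurements
#' (codes `V1`..`V121`) spanning 46 bones. Each entry records the bone, the
#' measurement label, the anatomical region, and whether the element is
#' bilateral (paired) or midline (vertebrae, sternum, sacrum). All
#' measurements are lengths in millimetres.
#'
#' @return A data.frame with columns `code`, `bone`, `label`, `region`,
#'   `bilateral` (logical) and `unit` (always `"mm"`).
#' @examples
#' reg <- osteo_registry()
#' nrow(reg)                       # 121
#' length(unique(reg$bone))        # 46
#' @export
osteo_registry <- function() {
  if (is.null(.osteosex_cache$registry)) {
    path <- system.file("extdata", "measurement_registry.csv",
                        package = "osteosex", mustWork = TRUE)
    reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "logical"))
    reg$unit <- "mm"
    stopifnot(!anyDuplicated(reg$code), nrow(reg) == 121L)
    .osteosex_cache$registry <- reg
  }
  .osteosex_cache$registry
}

#' Look up registry entries by code
#'
#' @param codes character vector of measurement codes (`"V1"`..`"V121"`).
#' @return the matching registry rows, in the order requested.
#' @export
registry_entry <- function(codes) {
  reg <- osteo_registry()
  idx <- match(codes, reg$code)
  if (anyNA(idx)) {
    stopf("unknown measurement code(s): %s",
          paste(codes[is.na(idx)], collapse = ", "))
  }
  reg[idx, , drop = FALSE]
}

#' Codes belonging to one bone
#'
#' @param bone bone name as in the registry (e.g. `"CLAVICLE"`, `"MT1"`).
#' @return character vector of measurement codes for that bone.
#' @export
bone_codes <- function(bone) {
  reg <- osteo_registry()
  if (!bone %in% reg$bone) stopf("unknown bone: %s", bone)
  reg$code[reg$bone == bone]
}

#' Export the registry as JSON
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(osteo_registry(), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
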