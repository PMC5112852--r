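#' Derive a stage-specific child seed from a global seed
#'
#' Deterministic fan-out of one user-facing seed into independent
#' per-stage seeds, keyed by a stage name, so adding a stage never shifts
#' another stage's random stream. The result always lies in
#' [1, 2^31 - 2].
#'
#' @param seed integer global seed
#' @param stage character stage name
#' @return an integer seed
#' @examples
#' deriveSeed(1, "permutations") != deriveSeed(1, "cv")
#' @export
deriveSeed <- function(seed, stage) {
    h <- 0
    for (ch in utf8ToInt(stage))
        h <- (h * 31 + ch) %% 1000003
    as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483646 + 1)
}

#' Write a run manifest as JSON
#'
#' @param manifest a named list of resolved parameters
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}
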