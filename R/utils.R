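## Shared helpers.

## Deterministic substream derivation: one user-facing seed drives every
## stochastic component through fixed offsets, so a whole pipeline run is
## reproducible from a single integer. Kept below 2^31 - 1.
.substream <- function(seed, offset) {
    s <- (as.double(seed) %% 2147483629) + 1
    as.integer((s * 48271 + offset * 16807) %% 2147483647)
}

.stopifnot_prob <- function(x, what) {
    if (anyNA(x) || any(x < 0) || any(x > 1))
        stop(what, " must lie in [0, 1]")
    invisible(x)
}

#' The study's three canonical contrasts
#'
#' Mono- versus co-culture within each cell type, plus the co-culture
#' versus co-culture comparison across cell types. In every contrast the
#' first-listed group is the numerator of the log2 fold change, so
#' \code{"UP"} in a mono-vs-co contrast means higher in monoculture.
#'
#' @return A named list of contrast specs, each a list with elements
#'   \code{name}, \code{first} and \code{second} (character(2):
#'   cell type, culture).
#' @examples
#' names(studyContrasts())
#' @export
studyContrasts <- function() {
    list(
        IMAdC_mono_vs_co = list(name = "IMAdC_mono_vs_co",
                                first = c("IMAdC", "mono"),
                                second = c("IMAdC", "co")),
        co_IMAdC_vs_co_SMSC = list(name = "co_IMAdC_vs_co_SMSC",
                                   first = c("IMAdC", "co"),
                                   second = c("SMSC", "co")),
        SMSC_mono_vs_co = list(name = "SMSC_mono_vs_co",
                               first = c("SMSC", "mono"),
                               second = c("SMSC", "co"))
    )
}

.group_samples <- function(sheet, group) {
    sheet$sample_id[sheet$cell_type == group[1L] &
                    sheet$culture == group[2L]]
}
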