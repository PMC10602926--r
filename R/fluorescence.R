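#' Reporter-fluorescence ratio normalization
#'
#' For each animal, divides the mean oocyte-nucleus intensity by the mean
#' intensity of reference areas in the distal gonad (where the repressor
#' is absent), giving one normalized expression ratio per animal. The
#' ovulating (-1) oocyte -- conventionally the last oocyte entry recorded
#' per animal -- can be excluded. If the table carries a two-level
#' `group` column (e.g. reporter strains), the per-animal ratios of the
#' two groups are compared with [rank_sum_test()].
#'
#' @param intensities data frame with columns `animal`, `compartment`
#'   (`"oocyte"` or `"distal"`), `value`, and optionally `group`.
#' @param exclude_last drop the last oocyte entry of each animal (the -1
#'   oocyte) before averaging.
#' @return List with `per_animal` (data frame: `animal`, `group` if
#'   present, `ratio`) and, when two groups are present, `comparison` (a
#'   `rank_sum_result`).
#' @export
fluorescence_ratio <- function(intensities, exclude_last = FALSE) {
  stopifnot(all(c("animal", "compartment", "value") %in% names(intensities)))
  if (!all(intensities$compartment %in% c("oocyte", "distal")))
    input_error("compartment must be 'oocyte' or 'distal'")
  has_group <- "group" %in% names(intensities)
  animals <- unique(intensities$animal)
  rows <- lapply(animals, function(a) {
    d <- intensities[intensities$animal == a, ]
    oo <- d$value[d$compartment == "oocyte"]
    di <- d$value[d$compartment == "distal"]
    if (!length(oo) || !length(di))
      input_error("animal '%s' lacks oocyte or distal measurements", a)
    if (exclude_last && length(oo) > 1L) oo <- oo[-length(oo)]
    if (mean(di) <= 0)
      input_error("animal '%s': distal mean <= 0", a)
    data.frame(animal = a,
               group = if (has_group) d$group[1] else NA_character_,
               ratio = mean(oo) / mean(di))
  })
  per <- do.call(rbind, rows)
  if (!has_group) per$group <- NULL
  out <- list(per_animal = per)
  if (has_group && length(unique(per$group)) == 2L) {
    g <- split(per$ratio, per$group)
    out$comparison <- rank_sum_test(g[[1]], g[[2]])
    out$groups <- names(g)
  }
  out
}
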