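#' Percent with half-up rounding
#'
#' Integer percent of `num / den`, rounding .5 upwards (the convention that
#' reproduces printed study tallies such as 134/736 -> 18 and 80/252 -> 32;
#' contrast with R's round-half-even `round()`).
#'
#' @param num,den Numerator and denominator (vectorized; `den > 0`).
#' @return Integer percent.
#' @export
percent_half_up <- function(num, den) {
  stopifnot(all(den > 0))
  as.integer(floor(100 * num / den + 0.5))
}

dedup_ledger <- function(ledger) {
  unique(ledger[, intersect(
    c("isolate_id", "phylum", "region_id", "species_cluster", "condition",
      "induced", "quality"), names(ledger)), drop = FALSE])
}

#' Summarize induction at isolate, prediction or species level
#'
#' Counts entities induced in at least one condition over entities eligible
#' at the level: all isolates, high-quality predictions only, or species
#' clusters of high-quality predictions only.
#'
#' @param ledger Data frame with one row per (isolate, region, condition)
#'   tested: `isolate_id`, `region_id`, `species_cluster`, `condition`,
#'   `induced` (logical), `quality` (`"high"`/`"low"`). Duplicated rows are
#'   dropped.
#' @param level `"isolate"`, `"prediction"` or `"species"`.
#' @return One-row data frame: `level`, `n_induced`, `n_total`, `percent`
#'   (half-up integer).
#' @export
summarize_induction <- function(ledger,
                                level = c("isolate", "prediction", "species")) {
  level <- match.arg(level)
  ledger <- dedup_ledger(ledger)
  if (level != "isolate") {
    if (!"quality" %in% names(ledger)) stop("ledger lacks a quality column")
    ledger <- ledger[ledger$quality == "high", , drop = FALSE]
  }
  key <- switch(level, isolate = "isolate_id", prediction = "region_id",
                species = "species_cluster")
  if (nrow(ledger) == 0L) stop("no eligible entities at level ", level)
  induced_by <- tapply(ledger$induced, ledger[[key]], any)
  n_total <- length(induced_by)
  n_induced <- sum(induced_by)
  data.frame(level = level, n_induced = n_induced, n_total = n_total,
             percent = percent_half_up(n_induced, n_total))
}

#' Per-condition induction counts and overlap with the standard medium
#'
#' Counts prophages induced under each condition and, for each condition,
#' how many of those were also induced in the standard growth medium
#' (spontaneous induction), quantifying how much an induction agent adds
#' over the spontaneous background.
#'
#' @param ledger Induction ledger (see [summarize_induction()]).
#' @param standard Label of the standard-medium condition.
#' @param conditions Allowed condition vocabulary; defaults to the labels
#'   present. Rows with labels outside it are rejected.
#' @return Data frame per condition: `n_induced`, `overlap_with_standard`.
#' @export
condition_overlap <- function(ledger, standard = "standard",
                              conditions = NULL) {
  ledger <- dedup_ledger(ledger)
  if (is.null(conditions)) conditions <- sort(unique(ledger$condition))
  if (!all(ledger$condition %in% conditions))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(ledger$condition), conditions), collapse = ", "))
  induced <- ledger[ledger$induced, , drop = FALSE]
  std_regions <- unique(induced$region_id[induced$condition == standard])
  res <- lapply(conditions, function(cond) {
    regs <- unique(induced$region_id[induced$condition == cond])
    data.frame(condition = cond, n_induced = length(regs),
               overlap_with_standard = length(intersect(regs, std_regions)))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Polylysogeny statistics
#'
#' A lysogen here is an isolate with at least one experimentally induced
#' prophage; a polylysogen has two or more. Emits the per-isolate inducible
#' prophage counts, the 2x2 contingency of polylysogeny (focal phylum vs
#' all others, among lysogens) and the per-prophage pairing of co-resident
#' inducible prophage count with the number of inducing conditions, ready
#' for downstream correlation tests.
#'
#' @param ledger Induction ledger with `isolate_id`, `phylum`, `region_id`,
#'   `condition`, `induced`.
#' @param focal_phylum Phylum contrasted against the rest (default
#'   `"Bacteroidota"`).
#' @return List with `per_isolate` (isolate, phylum, `n_inducible`,
#'   `is_lysogen`, `is_polylysogen`), `contingency` (2x2 matrix), and
#'   `per_prophage` (region, isolate, `n_coresident_inducible`,
#'   `n_conditions_induced`).
#' @export
polylysogeny_table <- function(ledger, focal_phylum = "Bacteroidota") {
  ledger <- dedup_ledger(ledger)
  induced <- ledger[ledger$induced, , drop = FALSE]
  iso <- unique(ledger[, c("isolate_id", "phylum")])
  n_ind <- tapply(induced$region_id, induced$isolate_id,
                  function(r) length(unique(r)))
  iso$n_inducible <- ifelse(iso$isolate_id %in% names(n_ind),
                            as.integer(n_ind[iso$isolate_id]), 0L)
  iso$is_lysogen <- iso$n_inducible >= 1L
  iso$is_polylysogen <- iso$n_inducible >= 2L
  lys <- iso[iso$is_lysogen, , drop = FALSE]
  contingency <- matrix(
    c(sum(lys$phylum == focal_phylum & lys$is_polylysogen),
      sum(lys$phylum == focal_phylum & !lys$is_polylysogen),
      sum(lys$phylum != focal_phylum & lys$is_polylysogen),
      sum(lys$phylum != focal_phylum & !lys$is_polylysogen)),
    nrow = 2, dimnames = list(c("polylysogen", "single_lysogen"),
                              c(focal_phylum, "other")))
  n_cond <- tapply(induced$condition, induced$region_id,
                   function(x) length(unique(x)))
  per_prophage <- data.frame(
    region_id = names(n_cond),
    isolate_id = induced$isolate_id[match(names(n_cond), induced$region_id)],
    n_conditions_induced = as.integer(n_cond), row.names = NULL)
  per_prophage$n_coresident_inducible <-
    iso$n_inducible[match(per_prophage$isolate_id, iso$isolate_id)]
  rownames(iso) <- NULL
  list(per_isolate = iso, contingency = contingency,
       per_prophage = per_prophage)
}
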