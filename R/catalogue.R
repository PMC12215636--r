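#' @name catalogue-format
#' @title Burial catalogue format
#' @description
#' A burial catalogue is a pair of data frames:
#'
#' * `records`: one row per buried individual, with columns `individual_id`,
#'   `site_id`, `region` (one of `NE`, `NW`, `SE`), `tier` (dating-confidence
#'   tier used by the models: `direct`, `medium` or `poor`), `c14_age` and
#'   `c14_error` (the direct determination, present iff `tier == "direct"`),
#'   and optional pass-through metadata (`tier_published`, `age_category`,
#'   `sex`, `period_label`, `reference`). `tier_published`, where present,
#'   carries an independently published confidence tally that need not agree
#'   with `tier`; both tallies are reported by [summarize_catalogue()],
#'   never reconciled.
#' * `site_dates`: one row per radiocarbon date associated with a site
#'   (typically charcoal from the occupation deposits), with columns
#'   `site_id`, `lab_id`, `c14_age`, `c14_error`, `material`.
#'
#' Individuals in the `medium` and `poor` tiers carry no determination of
#' their own; their ages enter the models as simulated determinations drawn
#' from the site-occupation chronology estimated from `site_dates`.
NULL

REGIONS <- c("NE", "NW", "SE")
TIERS <- c("direct", "medium", "poor")

#' Read a burial catalogue from CSV
#'
#' Validates the schema described in [catalogue-format]: mandatory columns
#' present, regions and tiers drawn from their vocabularies, and a direct
#' determination present exactly for `tier == "direct"` rows. Records with a
#' missing region or no usable dating evidence are dropped from the returned
#' record set but counted (a catalogue's published totals must stay
#' auditable); the dropped tally is attached as attribute `"n_dropped"`.
#'
#' @param burials_path CSV of individuals.
#' @param sites_path CSV of site-associated radiocarbon dates.
#' @return A list with elements `records` and `site_dates`.
#' @export
read_catalogue <- function(burials_path, sites_path) {
  records <- utils::read.csv(burials_path, stringsAsFactors = FALSE)
  site_dates <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  validate_catalogue(records, site_dates)
}

#' @rdname read_catalogue
#' @param records,site_dates in-memory data frames to validate.
#' @export
validate_catalogue <- function(records, site_dates) {
  need <- c("individual_id", "site_id", "region", "tier", "c14_age", "c14_error")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("burial table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  need_s <- c("site_id", "c14_age", "c14_error")
  missing_s <- setdiff(need_s, names(site_dates))
  if (length(missing_s))
    stop("site-date table lacks mandatory column(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)

  bad_region <- !is.na(records$region) & !(records$region %in% REGIONS)
  if (any(bad_region))
    stop("unknown region label(s) for individual(s): ",
         paste(records$individual_id[bad_region], collapse = ", "),
         call. = FALSE)
  bad_tier <- !is.na(records$tier) & !(records$tier %in% TIERS)
  if (any(bad_tier))
    stop("unknown tier label(s) for individual(s): ",
         paste(records$individual_id[bad_tier], collapse = ", "), call. = FALSE)

  has_date <- !is.na(records$c14_age) & !is.na(records$c14_error)
  direct <- !is.na(records$tier) & records$tier == "direct"
  if (any(direct & !has_date))
    stop("tier=direct without a determination for individual(s): ",
         paste(records$individual_id[direct & !has_date], collapse = ", "),
         call. = FALSE)
  if (any(has_date & records$c14_error <= 0, na.rm = TRUE))
    stop("non-positive c14_error for individual(s): ",
         paste(records$individual_id[which(has_date & records$c14_error <= 0)],
               collapse = ", "), call. = FALSE)

  # analysis eligibility: a region, and either a direct date or a site with
  # at least one associated date
  dated_sites <- unique(site_dates$site_id)
  eligible <- !is.na(records$region) & !is.na(records$tier) &
    (direct | records$site_id %in% dated_sites)
  dropped <- sum(!eligible)
  if (dropped)
    warning(sprintf("%d record(s) lack region or usable dating evidence and are excluded from analysis",
                    dropped), call. = FALSE)
  out <- list(records = records[eligible, , drop = FALSE],
              site_dates = site_dates)
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a burial catalogue to CSV
#'
#' @param catalogue a list with `records` and `site_dates` (and optionally
#'   `truth`, written alongside).
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_catalogue <- function(catalogue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(burials = file.path(dir, "burials.csv"),
             site_dates = file.path(dir, "site_dates.csv"))
  utils::write.csv(catalogue$records, paths["burials"], row.names = FALSE)
  utils::write.csv(catalogue$site_dates, paths["site_dates"], row.names = FALSE)
  if (!is.null(catalogue$truth)) {
    paths <- c(paths, truth = file.path(dir, "ground_truth.csv"))
    utils::write.csv(catalogue$truth, paths["truth"], row.names = FALSE)
  }
  invisible(paths)
}

#' Summarize a burial catalogue
#'
#' Counts of individuals by confidence tier, region, and region x tier, plus
#' the per-region percentage of indirectly dated (simulated-age) records.
#' When the records carry a `tier_published` column, the independently
#' published tally is reported alongside the analysis tally; the two are not
#' reconciled.
#'
#' @param records burial record data frame.
#' @return A list of class `catalogue_summary`.
#' @export
summarize_catalogue <- function(records) {
  tier <- factor(records$tier, levels = TIERS)
  region <- factor(records$region, levels = REGIONS)
  n_by_region <- table(region)
  sim <- tier %in% c("medium", "poor")
  pct_sim <- 100 * tapply(sim, region, mean)
  pct_sim[is.na(pct_sim)] <- 0
  out <- list(
    n_individuals = nrow(records),
    n_sites = length(unique(records$site_id)),
    n_by_tier = table(tier),
    n_by_region = n_by_region,
    n_by_region_tier = table(region, tier),
    pct_simulated_by_region = pct_sim
  )
  if ("tier_published" %in% names(records)) {
    tp <- factor(records$tier_published, levels = TIERS)
    out$n_by_tier_published <- table(tp)
    out$n_unclassified_published <- sum(is.na(tp))
  }
  structure(out, class = "catalogue_summary")
}

#' @export
print.catalogue_summary <- function(x, ...) {
  cat(sprintf("Burial catalogue: %d individuals, %d sites\n",
              x$n_individuals, x$n_sites))
  cat("  by tier (analysis):  ",
      paste(sprintf("%s=%d", names(x$n_by_tier), x$n_by_tier), collapse = ", "),
      "\n")
  if (!is.null(x$n_by_tier_published))
    cat("  by tier (published): ",
        paste(sprintf("%s=%d", names(x$n_by_tier_published),
                      x$n_by_tier_published), collapse = ", "),
        sprintf(" (+%d unclassified)\n", x$n_unclassified_published))
  cat("  by region: ",
      paste(sprintf("%s=%d", names(x$n_by_region), x$n_by_region),
            collapse = ", "), "\n")
  cat("  % simulated ages: ",
      paste(sprintf("%s=%.1f%%", names(x$pct_simulated_by_region),
                    x$pct_simulated_by_region), collapse = ", "), "\n")
  invisible(x)
}

#' Filter burial records by region, confidence tier, or site exclusion
#'
#' `tier_max` keeps records up to the named confidence level, so the three
#' progressive models nest: `direct` is a subset of `medium`, which is a
#' subset of `poor` (= everything). `exclude_sites` removes the *simulated*
#' (non-direct) records of the named sites only — directly dated individuals
#' from those sites are retained — mirroring the exclusion experiment used to
#' gauge the leverage of a few large assemblages.
#'
#' @param records burial record data frame.
#' @param region optional region label(s) to keep.
#' @param tier_max optional maximum confidence tier to keep.
#' @param exclude_sites optional site ids whose non-direct records are
#'   removed; unknown ids raise a warning, not an error.
#' @return The filtered data frame.
#' @export
filter_records <- function(records, region = NULL, tier_max = NULL,
                           exclude_sites = NULL) {
  out <- records
  if (!is.null(region)) out <- out[out$region %in% region, , drop = FALSE]
  if (!is.null(tier_max)) {
    tier_max <- match.arg(tier_max, TIERS)
    keep <- TIERS[seq_len(match(tier_max, TIERS))]
    out <- out[out$tier %in% keep, , drop = FALSE]
  }
  if (!is.null(exclude_sites)) {
    unknown <- setdiff(exclude_sites, records$site_id)
    if (length(unknown))
      warning("exclude_sites not present in catalogue: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    drop <- out$site_id %in% exclude_sites & out$tier != "direct"
    out <- out[!drop, , drop = FALSE]
  }
  out
}
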