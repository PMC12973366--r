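# QC and benchmarking summaries: missed-cleavage rate, labeling efficiency,
# four-set overlap (Venn) counts, spike-in accuracy / compression index, and
# protein-level CVs.

#' Fraction of peptides with zero missed cleavages
#'
#' @param peptides A [digest()]-style data.frame (or anything with a
#'   `missed_cleavages` column).
#' @return Fraction in \[0, 1\].
#' @export
missed_cleavage_rate <- function(peptides) {
  mc <- peptides$missed_cleavages
  if (is.null(mc) || length(mc) == 0L)
    stop("need a non-empty peptide set with missed_cleavages", call. = FALSE)
  mean(mc == 0L)
}

#' Isobaric labeling efficiency
#'
#' Per-site (default): fraction of labelable sites (peptide N-termini plus
#' lysines) that carry the label. Per-PSM alternative: fraction of peptides
#' whose labelable sites are all labeled.
#'
#' @param peptides A data.frame with integer columns `labelable_sites` and
#'   `labeled_sites` (one row per peptide/PSM).
#' @param per_psm Logical; when TRUE report the fully-labeled-peptide
#'   fraction instead of the site-level fraction.
#' @return Fraction in \[0, 1\].
#' @export
labeling_efficiency <- function(peptides, per_psm = FALSE) {
  stopifnot(is.data.frame(peptides),
            all(c("labelable_sites", "labeled_sites") %in% names(peptides)))
  if (any(peptides$labeled_sites > peptides$labelable_sites))
    stop("labeled_sites exceeds labelable_sites", call. = FALSE)
  total <- sum(peptides$labelable_sites)
  if (total == 0L) stop("zero labelable sites", call. = FALSE)
  if (per_psm) {
    has <- peptides$labelable_sites > 0L
    mean(peptides$labeled_sites[has] == peptides$labelable_sites[has])
  } else {
    sum(peptides$labeled_sites) / total
  }
}

#' Disjoint overlap (Venn) region counts for four named sets
#'
#' Partitions the union of four sets into the 15 disjoint Venn regions and
#' counts elements per region. Region names join member set names with
#' `"&"` (e.g. `"A&C"` = in A and C only).
#'
#' @param protein_sets Named list of exactly 4 character vectors with
#'   distinct names.
#' @return Named integer vector over the 15 regions; the counts sum to the
#'   union size. Attribute `union_size` carries the union size.
#' @export
overlap_counts <- function(protein_sets) {
  if (length(protein_sets) != 4L || is.null(names(protein_sets)) ||
      anyDuplicated(names(protein_sets)) || any(!nzchar(names(protein_sets))))
    stop("need exactly 4 uniquely named sets", call. = FALSE)
  nm <- names(protein_sets)
  sets <- lapply(protein_sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  region_names <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 4L))[-1L, ],
                        1L, function(m) paste(nm[unlist(m)], collapse = "&"))
  counts <- stats::setNames(integer(15L), region_names)
  if (length(universe)) {
    key <- apply(membership, 1L, function(m) paste(nm[m], collapse = "&"))
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
  }
  attr(counts, "union_size") <- length(universe)
  counts
}

#' Spike-in quantification accuracy summary
#'
#' Summarizes the output of [spike_log2_ratios()]: the median log2 ratio over
#' all (protein, channel) pairs, per-channel medians, and the compression
#' index `1 - median / expected` (0 = no compression, approaching 1 = full
#' compression toward the population mean). The compression index is this
#' package's derived summary of ratio compression, not a community-standard
#' statistic.
#'
#' @param ratios A data.frame from [spike_log2_ratios()] (or with columns
#'   `log2_ratio` and optionally `subplex`, `channel`).
#' @param expected Expected log2 ratio (default 1, the 2:1 spike design).
#' @return List with `median`, `per_channel` (data.frame of per
#'   subplex/channel medians) and `compression_index` (NA when
#'   `expected == 0`).
#' @export
spike_accuracy <- function(ratios, expected = 1) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 1L)
  med <- stats::median(ratios$log2_ratio)
  per_channel <- NULL
  if (all(c("subplex", "channel") %in% names(ratios))) {
    agg <- stats::aggregate(log2_ratio ~ subplex + channel, data = ratios,
                            FUN = stats::median)
    names(agg)[names(agg) == "log2_ratio"] <- "median_log2_ratio"
    per_channel <- agg
  }
  idx <- if (expected == 0) NA_real_ else 1 - med / expected
  list(median = med, per_channel = per_channel, compression_index = idx)
}

#' Median protein-level coefficient of variation
#'
#' CV per protein = population sd / mean on the linear (bridge-anchored)
#' scale over the columns of a replicate group; the summary is the median CV
#' across proteins, reported per scope. Groups of size 1 are excluded with a
#' warning.
#'
#' @param values Numeric matrix (proteins x columns) of linear-scale
#'   abundances.
#' @param groups Named list: group label -> character vector of column names
#'   forming a replicate group.
#' @return Named numeric vector of median CVs, one per group with >= 2
#'   members.
#' @export
protein_cv <- function(values, groups) {
  stopifnot(is.matrix(values), is.list(groups), !is.null(names(groups)))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- numeric(0)
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) < 2L) {
      warning("group '", g, "' has fewer than 2 members; excluded",
              call. = FALSE)
      next
    }
    m <- values[, cols, drop = FALSE]
    cv <- apply(m, 1L, function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2L || mean(x) == 0) return(NA_real_)
      pop_sd(x) / mean(x)
    })
    out[g] <- stats::median(cv, na.rm = TRUE)
  }
  out
}

#' Replicate column groups of a design
#'
#' Builds the replicate groupings used for CV reporting: within-subplex
#' groups (same sample label repeated inside one subplex) and between-subplex
#' groups (same sample label across all subplexes).
#'
#' @param design A [plex_design()].
#' @param scope `"within"` or `"between"`.
#' @return Named list group label -> column names
#'   (`"<subplex>|<channel>"`).
#' @export
replicate_groups <- function(design, scope = c("within", "between")) {
  scope <- match.arg(scope)
  groups <- list()
  if (scope == "within") {
    for (sp in design$subplexes) {
      ac <- assigned_channels(sp)
      for (lab in unique(sp$assignments[ac])) {
        ch <- ac[sp$assignments[ac] == lab]
        groups[[paste(sp$id, lab, sep = ":")]] <-
          paste(sp$id, ch, sep = "|")
      }
    }
  } else {
    labs <- unique(unlist(lapply(design$subplexes, function(sp)
      sp$assignments[assigned_channels(sp)])))
    for (lab in labs) {
      cols <- unlist(lapply(design$subplexes, function(sp) {
        ac <- assigned_channels(sp)
        paste(sp$id, ac[sp$assignments[ac] == lab], sep = "|")
      }))
      groups[[lab]] <- cols
    }
  }
  groups
}

#' Assemble a QC report
#'
#' Collects the per-subplex digestion/labeling QC and the design-level
#' quantification benchmarks into one serializable report.
#'
#' @param per_subplex Named list (by subplex id) of lists with
#'   `frac_zero_missed_cleavage`, `labeling_efficiency_frac` and
#'   `specificity` (a [specificity_profile()]).
#' @param overlap Output of [overlap_counts()] (or NULL).
#' @param spike Named list (by acquisition, e.g. MS2/MS3) of
#'   [spike_accuracy()] outputs (or NULL).
#' @param cv_summaries Named list of [protein_cv()] outputs (or NULL).
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(per_subplex, overlap = NULL, spike = NULL,
                      cv_summaries = NULL) {
  structure(list(per_subplex = per_subplex,
                 overlap_counts = overlap,
                 spike = spike,
                 cv_summaries = cv_summaries),
            class = "qc_report")
}
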