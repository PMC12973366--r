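# The bridge-anchored normalization and integration chain:
# master-protein filtering -> zero replacement -> sample-wise median
# normalization + log2 -> bridge scaling -> global centering, with MAD
# harmonization across acquisition methods and raw-scale spike ratios.
# Steps are order-locked; every object carries a provenance log.

#' Pipeline parameters
#'
#' Numeric constants of the normalization and filtering chain.
#'
#' @param zero_replacement Value substituted for zeros before ratio/log steps
#'   (linear S/N; default 0.1).
#' @param min_nonzero_per_subplex Minimum nonzero values a protein needs
#'   within a subplex to count as quantified there (default 1).
#' @param bridge_channels The reporter labels carrying the bridge sample
#'   (default 126, 127N, 127C, 128N).
#' @param sn_filter_threshold Average reporter signal-to-noise threshold used
#'   upstream for PSM filtering (default 3; configuration passthrough — the
#'   simulator emits protein-level values that are already post-filter).
#' @param core_protein_rule Rule naming the core set used for cross-subplex
#'   centering; `"all_subplexes"` = quantified in every subplex.
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(zero_replacement = 0.1,
                            min_nonzero_per_subplex = 1L,
                            bridge_channels = c("126", "127N", "127C", "128N"),
                            sn_filter_threshold = 3,
                            core_protein_rule = "all_subplexes") {
  stopifnot(zero_replacement > 0, min_nonzero_per_subplex >= 1L)
  structure(list(zero_replacement = zero_replacement,
                 min_nonzero_per_subplex = as.integer(min_nonzero_per_subplex),
                 bridge_channels = bridge_channels,
                 sn_filter_threshold = sn_filter_threshold,
                 core_protein_rule = core_protein_rule),
            class = "pipeline_params")
}

provenance_of <- function(table) {
  p <- table$metadata$provenance
  if (is.null(p)) list() else p
}

provenance_steps <- function(table) {
  vapply(provenance_of(table), `[[`, character(1L), "step")
}

add_provenance <- function(table, step, params = list()) {
  table$metadata$provenance <- c(provenance_of(table),
                                 list(list(step = step, params = params)))
  table
}

require_step <- function(table, needed, before) {
  if (!(needed %in% provenance_steps(table)))
    stop("pipeline-order error: '", before, "' requires '", needed,
         "' to have been applied first", call. = FALSE)
}

#' Filter to master proteins quantified within subplexes
#'
#' Drops proteins with fewer than `min_nonzero_per_subplex` nonzero values in
#' every subplex (i.e. quantified nowhere); when `subplex` names a single
#' subplex, drops proteins not quantified in that subplex. Also records,
#' per protein, which subplexes quantify it and flags the core set
#' (quantified in all subplexes), which the global centering step uses.
#'
#' @param table A `quant_table`.
#' @param params A [pipeline_params()].
#' @param subplex Optional subplex id restricting the filter to one subplex.
#' @return The filtered `quant_table` with `metadata$quantified_in` (logical
#'   matrix protein x subplex) and `metadata$core` (logical vector).
#' @export
filter_master_proteins <- function(table, params = pipeline_params(),
                                   subplex = NULL) {
  stopifnot(inherits(table, "quant_table"))
  sps <- unique(table$columns$subplex)
  qmat <- vapply(sps, function(s) {
    cols <- table$columns$column[table$columns$subplex == s]
    rowSums(table$values[, cols, drop = FALSE] > 0) >=
      params$min_nonzero_per_subplex
  }, logical(nrow(table$values)))
  qmat <- matrix(qmat, nrow = nrow(table$values),
                 dimnames = list(rownames(table$values), sps))
  keep <- if (is.null(subplex)) rowSums(qmat) > 0 else qmat[, subplex]
  if (!any(keep))
    warning("no proteins pass the master-protein filter", call. = FALSE)
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$species <- table$species[keep]
  out$metadata$quantified_in <- qmat[keep, , drop = FALSE]
  out$metadata$core <- rowSums(qmat[keep, , drop = FALSE]) == length(sps)
  add_provenance(out, "filter_master_proteins",
                 list(min_nonzero_per_subplex = params$min_nonzero_per_subplex,
                      subplex = subplex))
}

#' Replace zero (missing) values with a floor
#'
#' Every 0 becomes `params$zero_replacement` (default 0.1) so that ratios and
#' logs are defined; nonzero values are untouched. Idempotent.
#'
#' @param table A `quant_table`.
#' @param params A [pipeline_params()].
#' @return The `quant_table` with zeros replaced and `metadata$imputed`
#'   marking replaced entries.
#' @export
replace_zeros <- function(table, params = pipeline_params()) {
  stopifnot(inherits(table, "quant_table"))
  require_step(table, "filter_master_proteins", "replace_zeros")
  if (any(table$values < 0))
    stop("negative signal-to-noise values are invalid", call. = FALSE)
  out <- table
  imputed <- table$values == 0
  prior <- out$metadata$imputed
  out$metadata$imputed <- if (is.null(prior)) imputed else prior | imputed
  out$values[imputed] <- params$zero_replacement
  add_provenance(out, "replace_zeros",
                 list(zero_replacement = params$zero_replacement))
}

#' Sample-wise median normalization and log2 transform
#'
#' Each column is scaled so that its median equals the grand median of all
#' column medians (a scale-preserving target), then log2 is applied. After
#' this step all column medians are equal on the log2 scale.
#'
#' @param table A `quant_table` with strictly positive values (run
#'   [replace_zeros()] first).
#' @return A `normalized_table`: same container with log2 values and the step
#'   appended to the provenance log.
#' @export
median_normalize_log2 <- function(table) {
  stopifnot(inherits(table, "quant_table") ||
              inherits(table, "normalized_table"))
  require_step(table, "replace_zeros", "median_normalize_log2")
  if (any(table$values <= 0))
    stop("pipeline-order error: nonpositive values reached ",
         "median_normalize_log2; apply replace_zeros first", call. = FALSE)
  med <- apply(table$values, 2L, stats::median)
  grand <- stats::median(med)
  out <- table
  out$values <- log2(sweep(table$values, 2L, grand / med, `*`))
  out <- add_provenance(out, "median_normalize_log2",
                        list(grand_median = grand))
  class(out) <- "normalized_table"
  out
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table> %d proteins x %d channels; steps: %s\n",
              nrow(x$values), ncol(x$values),
              paste(provenance_steps(x), collapse = " -> ")))
  invisible(x)
}

bridge_columns <- function(table, design) {
  lapply(stats::setNames(design$subplexes,
                         vapply(design$subplexes, `[[`, character(1L), "id")),
         function(sp) {
           cols <- table$columns[table$columns$subplex == sp$id, ]
           bc <- cols$column[cols$channel %in% sp$bridge_channels]
           if (length(bc) < length(sp$bridge_channels))
             stop("subplex ", sp$id, ": bridge channel(s) missing from the ",
                  "quant table", call. = FALSE)
           bc
         })
}

#' Bridge-channel scaling
#'
#' Anchors every subplex to the common bridge sample. Row-wise (default, the
#' internal-reference-scaling reading): for each protein and subplex,
#' subtract the mean of that protein's bridge-channel log2 values from all of
#' the subplex's columns, making the protein's bridge mean exactly 0 in every
#' subplex. Column-wise alternative: subtract one per-subplex scalar (the
#' grand mean of the bridge columns) from all the subplex's columns.
#'
#' @param table A `normalized_table` (after [median_normalize_log2()]).
#' @param design The [plex_design()] defining subplexes and bridge channels.
#' @param method `"row"` (per protein, default) or `"column"` (per-subplex
#'   scalar shift).
#' @return The scaled `normalized_table`; `metadata$bridge_imputed_rows`
#'   flags proteins whose bridge values include imputed zeros.
#' @export
bridge_scale <- function(table, design, method = c("row", "column")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "normalized_table"))
  require_step(table, "median_normalize_log2", "bridge_scale")
  bcols <- bridge_columns(table, design)
  out <- table
  flagged <- character()
  for (sp_id in names(bcols)) {
    sp_cols <- table$columns$column[table$columns$subplex == sp_id]
    bc <- bcols[[sp_id]]
    if (!is.null(table$metadata$imputed)) {
      imp <- rowSums(table$metadata$imputed[, bc, drop = FALSE]) > 0
      flagged <- union(flagged, rownames(table$values)[imp])
    }
    offset <- if (method == "row") {
      rowMeans(out$values[, bc, drop = FALSE])
    } else {
      mean(out$values[, bc, drop = FALSE])
    }
    out$values[, sp_cols] <- out$values[, sp_cols, drop = FALSE] - offset
  }
  out$metadata$bridge_imputed_rows <- flagged
  add_provenance(out, "bridge_scale", list(method = method))
}

#' Global centering across subplexes
#'
#' Centers each column at zero using only the core proteins (those quantified
#' in every subplex), so that columns from different subplexes share a common
#' zero without letting subplex-specific proteins shift it. Idempotent.
#'
#' @param table A `normalized_table` (after [bridge_scale()]).
#' @return The centered `normalized_table`.
#' @export
global_center <- function(table) {
  stopifnot(inherits(table, "normalized_table"))
  require_step(table, "bridge_scale", "global_center")
  core <- table$metadata$core
  if (is.null(core)) core <- rep(TRUE, nrow(table$values))
  if (!any(core))
    stop("core protein set is empty; supply a larger input (no protein is ",
         "quantified in all subplexes)", call. = FALSE)
  out <- table
  out$values <- sweep(table$values, 2L,
                      colMeans(table$values[core, , drop = FALSE]), `-`)
  add_provenance(out, "global_center", list(n_core = sum(core)))
}

#' MAD harmonization across acquisition methods
#'
#' Divides each column by its raw median absolute deviation (no 1.4826
#' consistency factor: the goal is dynamic-range equalization between
#' MS2-like and MS3-like tables, not sigma estimation). After this step every
#' column's raw MAD is 1.
#'
#' @param tables A `normalized_table` or list of them (e.g. MS2 and MS3).
#' @return Object(s) of the same shape with unit-MAD columns.
#' @export
mad_harmonize <- function(tables) {
  single <- inherits(tables, "normalized_table")
  if (single) tables <- list(tables)
  out <- lapply(tables, function(tab) {
    stopifnot(inherits(tab, "normalized_table"))
    require_step(tab, "global_center", "mad_harmonize")
    mads <- apply(tab$values, 2L, stats::mad, constant = 1)
    if (any(mads == 0))
      stop("zero MAD in column(s): ",
           paste(colnames(tab$values)[mads == 0], collapse = ", "),
           call. = FALSE)
    tab$values <- sweep(tab$values, 2L, mads, `/`)
    add_provenance(tab, "mad_harmonize", list())
  })
  if (single) out[[1L]] else out
}

#' Spike-in log2 ratios from raw signal-to-noise values
#'
#' For each E. coli spike-in protein and each high-spike channel, computes
#' log2(raw value / mean of the protein's nonzero low-spike channel values in
#' the same subplex). Computed on the raw (pre-normalization) table, as the
#' benchmark prescribes; zeros are treated as missing.
#'
#' @param table A raw `quant_table` containing E. coli rows.
#' @param design The [plex_design()] declaring per-channel spike amounts.
#' @return A `data.frame` with `protein_id`, `subplex`, `channel`,
#'   `log2_ratio`, `expected_log2`.
#' @export
spike_log2_ratios <- function(table, design) {
  stopifnot(inherits(table, "quant_table"))
  ec <- names(table$species)[table$species == "ecoli"]
  if (!length(ec)) stop("no E. coli proteins in the table", call. = FALSE)
  out <- list()
  for (sp in design$subplexes) {
    ac <- assigned_channels(sp)
    amounts <- sp$spike_ug[ac]
    lo_amt <- min(amounts); hi_amt <- max(amounts)
    lo_ch <- ac[amounts == lo_amt]
    hi_ch <- ac[amounts == hi_amt]
    if (!length(lo_ch) || lo_amt == hi_amt)
      stop("subplex ", sp$id, ": no low-spike channels (single spike level)",
           call. = FALSE)
    cols <- table$columns[table$columns$subplex == sp$id, ]
    lo_cols <- cols$column[match(lo_ch, cols$channel)]
    hi_cols <- cols$column[match(hi_ch, cols$channel)]
    vals <- table$values[ec, , drop = FALSE]
    lo_m <- vals[, lo_cols, drop = FALSE]
    lo_m[lo_m == 0] <- NA_real_
    lo_mean <- rowMeans(lo_m, na.rm = TRUE)
    for (j in seq_along(hi_cols)) {
      v <- vals[, hi_cols[j]]
      ok <- v > 0 & is.finite(lo_mean)
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        protein_id = ec[ok], subplex = sp$id, channel = hi_ch[j],
        log2_ratio = log2(v[ok] / lo_mean[ok]),
        expected_log2 = log2(hi_amt / lo_amt),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full normalization chain
#'
#' Applies, in the locked order: master-protein filter, zero replacement,
#' sample-wise median normalization + log2, bridge scaling, global centering.
#'
#' @param table A raw `quant_table`.
#' @param design The [plex_design()].
#' @param params A [pipeline_params()].
#' @param bridge_method Passed to [bridge_scale()].
#' @return A `normalized_table` whose provenance log records all five steps.
#' @export
normalize_pipeline <- function(table, design, params = pipeline_params(),
                               bridge_method = "row") {
  table <- filter_master_proteins(table, params)
  table <- replace_zeros(table, params)
  table <- median_normalize_log2(table)
  table <- bridge_scale(table, design, method = bridge_method)
  global_center(table)
}
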