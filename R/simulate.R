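# Two-species reporter-ion quantification simulator with an explicit
# coisolation-interference model. Observed = (1 - alpha) * true +
# alpha * background, where background is the within-subplex mean of the true
# values (a proxy for the coisolated precursor population); multiplicative
# log-normal noise and uniform missingness follow.

#' Noise model for the reporter-ion simulator
#'
#' @param interference_alpha Coisolation-interference fraction in \[0, 1\].
#'   0 = interference-free, 1 = complete ratio compression. The MS2-like
#'   default (0.35) exceeds the MS3-like default (0.08), reflecting the
#'   stronger compression of MS2 reporter quantification; the two defaults
#'   encode the ordering of the acquisition modes, not any particular
#'   measured compression level.
#' @param measurement_cv Multiplicative measurement noise as a coefficient of
#'   variation (log-normal, median 1).
#' @param sn_scale Factor mapping linear abundance to reporter
#'   signal-to-noise units.
#' @param missing_rate Fraction of entries set to 0 (missing) uniformly at
#'   random.
#' @param seed Integer seed driving the single RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(interference_alpha = 0.35, measurement_cv = 0.1,
                        sn_scale = 100, missing_rate = 0.05, seed = 1L) {
  stopifnot(interference_alpha >= 0, interference_alpha <= 1,
            measurement_cv >= 0, missing_rate >= 0, missing_rate <= 1,
            sn_scale > 0)
  structure(list(interference_alpha = interference_alpha,
                 measurement_cv = measurement_cv, sn_scale = sn_scale,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Default noise models per acquisition mode
#'
#' @param acquisition `"MS2"` or `"MS3"`.
#' @param seed Integer seed.
#' @return A [noise_model()] with the acquisition's default interference
#'   fraction (MS2 0.35, MS3 0.08).
#' @export
default_noise_model <- function(acquisition = c("MS2", "MS3"), seed = 1L) {
  acquisition <- match.arg(acquisition)
  noise_model(interference_alpha = if (acquisition == "MS2") 0.35 else 0.08,
              seed = seed)
}

#' Generate ground-truth protein abundances for a two-species design
#'
#' Human proteins receive a per-protein log-normal base abundance shared
#' across samples, modulated by per-(protein, cell line) log2-normal offsets
#' with standard deviation `cell_line_effect_sd`; the bridge sample is the
#' pool (mean) of the cell lines. E. coli spike-in proteins receive a
#' per-protein base abundance; their channel abundance is base x spike
#' micrograms, so the truth ratio between 1 and 0.5 microgram channels is
#' exactly 2.
#'
#' @param n_human,n_ecoli Protein counts (>= 1).
#' @param cell_lines Cell-line labels (the non-bridge sample labels).
#' @param cell_line_effect_sd Standard deviation of per-cell-line offsets in
#'   log2 units.
#' @param seed Integer seed.
#' @return An object of class `ground_truth`: `human` (matrix protein x
#'   sample, including a `BRIDGE` column), `ecoli_base` (named vector),
#'   `species` (named vector over all protein ids), `cell_line_effect_sd`,
#'   `seed`.
#' @export
make_ground_truth <- function(n_human, n_ecoli,
                              cell_lines = c("HT55", "LS1034", "MDST8",
                                             "SW948"),
                              cell_line_effect_sd = 0.5, seed = 1L) {
  stopifnot(n_human >= 1L, n_ecoli >= 1L, cell_line_effect_sd >= 0)
  set.seed(seed)
  hid <- sprintf("HUMAN_%04d", seq_len(n_human))
  eid <- sprintf("ECOLI_%04d", seq_len(n_ecoli))
  base <- exp(stats::rnorm(n_human, mean = log(100), sd = 1))
  offsets <- matrix(2^stats::rnorm(n_human * length(cell_lines),
                                   sd = cell_line_effect_sd),
                    nrow = n_human)
  human <- base * offsets
  human <- cbind(human, rowMeans(human))  # pooled bridge reference
  dimnames(human) <- list(hid, c(cell_lines, "BRIDGE"))
  ecoli_base <- stats::setNames(exp(stats::rnorm(n_ecoli, mean = log(50),
                                                 sd = 1)), eid)
  structure(list(human = human, ecoli_base = ecoli_base,
                 species = stats::setNames(
                   c(rep("human", n_human), rep("ecoli", n_ecoli)),
                   c(hid, eid)),
                 cell_line_effect_sd = cell_line_effect_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# true linear abundance matrix (all proteins x assigned channels) for one
# subplex: human rows look up the channel's sample label, E. coli rows are
# base x channel spike micrograms
true_subplex_matrix <- function(sp, truth) {
  ac <- assigned_channels(sp)
  samples <- sp$assignments[ac]
  missing_samples <- setdiff(unique(samples), colnames(truth$human))
  if (length(missing_samples))
    stop("ground truth lacks sample(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  h <- truth$human[, samples, drop = FALSE]
  e <- outer(truth$ecoli_base, sp$spike_ug[ac])
  m <- rbind(h, e)
  colnames(m) <- ac
  m
}

#' Simulate a protein x channel reporter quantification table
#'
#' For each protein and channel the observed signal is
#' `(1 - alpha) * true + alpha * background`, where `background` is the
#' protein's mean true abundance over the subplex's channels (the coisolated
#' population proxy); multiplicative log-normal noise with the stated CV is
#' applied, values are scaled to signal-to-noise units, and a `missing_rate`
#' fraction of entries is zeroed. Fully reproducible from the noise model's
#' seed. Simulated values are post isotope-impurity correction by
#' construction; no impurity mixing between reporter channels is modeled.
#'
#' @param design A validated [plex_design()].
#' @param truth A [make_ground_truth()] object covering all sample labels in
#'   the design.
#' @param noise A [noise_model()]; defaults to the acquisition's default.
#' @param acquisition `"MS2"` or `"MS3"` (metadata, and selects the default
#'   noise model when `noise` is NULL).
#' @return A `quant_table`: list with `values` (matrix, rows = proteins,
#'   columns = `"<subplex>|<channel>"`), `species` (named vector),
#'   `columns` (data.frame subplex/channel per column) and `metadata`
#'   (acquisition, seed, model parameters).
#' @export
simulate_quant <- function(design, truth, noise = NULL,
                           acquisition = c("MS2", "MS3")) {
  acquisition <- match.arg(acquisition)
  if (is.null(noise)) noise <- default_noise_model(acquisition)
  stopifnot(inherits(design, "plex_design"), inherits(truth, "ground_truth"),
            inherits(noise, "noise_model"))
  v <- validate_design(design)
  if (length(v)) stop("invalid design: ", v[1L], call. = FALSE)
  set.seed(noise$seed)
  sdlog <- sqrt(log(1 + noise$measurement_cv^2))
  blocks <- list()
  cols <- list()
  for (sp in design$subplexes) {
    true_m <- true_subplex_matrix(sp, truth)
    background <- rowMeans(true_m)
    obs <- (1 - noise$interference_alpha) * true_m +
      noise$interference_alpha * background
    if (noise$measurement_cv > 0)
      obs <- obs * exp(matrix(stats::rnorm(length(obs), sd = sdlog),
                              nrow = nrow(obs)))
    obs <- obs * noise$sn_scale
    if (noise$missing_rate > 0)
      obs[matrix(stats::runif(length(obs)) < noise$missing_rate,
                 nrow = nrow(obs))] <- 0
    colnames(obs) <- paste(sp$id, colnames(true_m), sep = "|")
    blocks[[sp$id]] <- obs
    cols[[sp$id]] <- data.frame(column = colnames(obs), subplex = sp$id,
                                channel = assigned_channels(sp),
                                stringsAsFactors = FALSE)
  }
  quant_table(values = do.call(cbind, blocks), species = truth$species,
              columns = do.call(rbind, cols),
              metadata = list(acquisition = acquisition, seed = noise$seed,
                              interference_alpha = noise$interference_alpha,
                              measurement_cv = noise$measurement_cv,
                              sn_scale = noise$sn_scale,
                              missing_rate = noise$missing_rate))
}

#' Construct a quant table container
#'
#' @param values Numeric matrix (proteins x channels), finite and >= 0
#'   (0 = missing), with `"<subplex>|<channel>"` column names.
#' @param species Named character vector protein id -> species.
#' @param columns `data.frame` with `column`, `subplex`, `channel`.
#' @param metadata List of acquisition/model metadata.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(values, species, columns, metadata = list()) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0),
            identical(colnames(values), columns$column),
            all(rownames(values) %in% names(species)))
  rownames(columns) <- NULL
  structure(list(values = values,
                 species = species[rownames(values)],
                 columns = columns, metadata = metadata),
            class = "quant_table")
}

#' Subset a quant table to selected proteins
#'
#' Keeps rows by protein id or species. The statistical chain is defined for
#' the human proteome (spike-in proteins are benchmarked separately on the
#' raw scale), so analyses typically run on
#' `subset_proteins(table, species = "human")`.
#'
#' @param table A `quant_table` or `normalized_table`.
#' @param ids Protein ids to keep (default: all).
#' @param species Optionally keep only rows of this species.
#' @return The subsetted table, row-level metadata realigned.
#' @export
subset_proteins <- function(table, ids = rownames(table$values),
                            species = NULL) {
  if (!is.null(species))
    ids <- intersect(ids, names(table$species)[table$species %in% species])
  keep <- rownames(table$values) %in% ids
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$species <- table$species[keep]
  for (field in c("imputed", "quantified_in"))
    if (!is.null(out$metadata[[field]]))
      out$metadata[[field]] <- out$metadata[[field]][keep, , drop = FALSE]
  if (!is.null(out$metadata$core))
    out$metadata$core <- out$metadata$core[keep]
  out
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d proteins (%d human, %d ecoli) x %d channels [%s]\n",
              nrow(x$values), sum(x$species == "human"),
              sum(x$species == "ecoli"), ncol(x$values),
              if (is.null(x$metadata$acquisition)) "?" else
                x$metadata$acquisition))
  invisible(x)
}
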