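# Readers and writers: FASTA (via Biostrings), design JSON/CSV, the quant
# table TSV dialect with its JSON metadata sidecar, QC report JSON, and the
# seeded fixture generator. Tabular files are tab-delimited UTF-8 with '.'
# decimal throughout.

#' Read protein sequences from a FASTA file
#'
#' Parses a standard multi-record FASTA via Biostrings; the accession is the
#' first whitespace-delimited token of the description line. Species is
#' assigned by regex on the full description (default: the substring
#' `"ECOLI"` marks E. coli, everything else is human).
#'
#' @param path Path to a FASTA file.
#' @param species_patterns Named character vector of regexes tried in order;
#'   the first match assigns its name as species. Names must be
#'   `"human"`, `"ecoli"` or `"other"`.
#' @param default_species Species assigned when no pattern matches.
#' @return List of [protein_sequence()] objects.
#' @export
read_fasta <- function(path, species_patterns = c(ecoli = "ECOLI"),
                       default_species = "human") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  lapply(seq_along(aa), function(i) {
    desc <- names(aa)[i]
    id <- strsplit(desc, "[ \t]")[[1L]][1L]
    species <- default_species
    for (sp in names(species_patterns))
      if (grepl(species_patterns[[sp]], desc)) { species <- sp; break }
    protein_sequence(id, as.character(aa[[i]]), species)
  })
}

#' Write a peptide table as TSV
#'
#' @param peptides A [digest()] or [peptide_ions()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_tsv <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a peptide table written by [write_peptides_tsv()]
#'
#' @param path Input path.
#' @return A peptide `data.frame`.
#' @export
read_peptides_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

design_to_list <- function(design) {
  list(
    cell_lines = design$cell_lines,
    subplexes = lapply(design$subplexes, function(sp) list(
      id = sp$id, protease = sp$protease, tag_set = sp$tag_set$name,
      channels = sp$tag_set$channels,
      assignments = as.list(sp$assignments),
      bridge_channels = sp$bridge_channels,
      spike_ug = as.list(sp$spike_ug)
    ))
  )
}

#' Write a plex design to JSON (canonical format)
#'
#' @param design A [plex_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(design_to_list(design), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a plex design from JSON
#'
#' @param path Path written by [write_design_json()].
#' @return A [plex_design()].
#' @export
read_design_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  subplexes <- lapply(x$subplexes, function(sp) {
    ts <- tag_set(sp$tag_set)
    subplex(sp$id, sp$protease, ts,
            assignments = unlist(sp$assignments),
            bridge_channels = unlist(sp$bridge_channels),
            spike_ug = unlist(sp$spike_ug))
  })
  plex_design(subplexes, unlist(x$cell_lines))
}

#' Write a plex design as a per-channel CSV
#'
#' One row per channel: subplex, protease, tag_set, channel, sample,
#' is_bridge, spike_ug. UNUSED channels are included so channel indices stay
#' aligned with the tag-set definition.
#'
#' @param design A [plex_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  rows <- do.call(rbind, lapply(design$subplexes, function(sp) data.frame(
    subplex = sp$id, protease = sp$protease, tag_set = sp$tag_set$name,
    channel = sp$tag_set$channels,
    sample = unname(sp$assignments[sp$tag_set$channels]),
    is_bridge = sp$tag_set$channels %in% sp$bridge_channels,
    spike_ug = unname(sp$spike_ug[sp$tag_set$channels]),
    stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plex design from the per-channel CSV
#'
#' @param path Path written by [write_design_csv()].
#' @param cell_lines Optional explicit cell-line labels; by default the
#'   distinct non-bridge, non-UNUSED sample labels.
#' @return A [plex_design()].
#' @export
read_design_csv <- function(path, cell_lines = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(channel = "character"))
  subplexes <- lapply(split(x, factor(x$subplex, unique(x$subplex))),
                      function(d) {
    subplex(d$subplex[1L], d$protease[1L], tag_set(d$tag_set[1L]),
            assignments = stats::setNames(d$sample, d$channel),
            bridge_channels = d$channel[d$is_bridge],
            spike_ug = stats::setNames(d$spike_ug, d$channel))
  })
  if (is.null(cell_lines))
    cell_lines <- sort(unique(x$sample[!x$is_bridge & x$sample != "UNUSED"]))
  plex_design(unname(subplexes), cell_lines)
}

#' Write a quant table as TSV with a JSON metadata sidecar
#'
#' First columns `protein_id`, `species`; remaining columns are named
#' `"<subplex>|<channel>"`. Metadata (acquisition, seed, model parameters,
#' provenance) goes to `<path>.meta.json`.
#'
#' @param table A `quant_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  df <- data.frame(protein_id = rownames(table$values),
                   species = unname(table$species),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(columns = table$columns,
         metadata = table$metadata[setdiff(names(table$metadata),
                                           c("imputed", "quantified_in"))]),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a quant table TSV (with optional sidecar)
#'
#' When the `<path>.meta.json` sidecar is absent, subplex and channel are
#' recovered from the `"<subplex>|<channel>"` column names.
#'
#' @param path TSV path written by [write_quant_tsv()] (or the same dialect
#'   exported elsewhere).
#' @return A `quant_table`.
#' @export
read_quant_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "species")
  if (!all(need %in% names(df)[1:2]))
    stop("quant TSV must start with columns protein_id, species: ", path,
         call. = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$protein_id
  meta_path <- paste0(path, ".meta.json")
  metadata <- list()
  if (file.exists(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    metadata <- as.list(side$metadata)
    columns <- side$columns
  } else {
    parts <- strsplit(colnames(vals), "|", fixed = TRUE)
    columns <- data.frame(column = colnames(vals),
                          subplex = vapply(parts, `[`, "", 1L),
                          channel = vapply(parts, `[`, "", 2L),
                          stringsAsFactors = FALSE)
  }
  quant_table(vals, stats::setNames(df$species, df$protein_id),
              columns, metadata)
}

#' Write a QC report to JSON and a TSV summary
#'
#' @param report A [qc_report()].
#' @param path Output JSON path; a human-readable summary is written next to
#'   it as `<path>.summary.tsv`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  ser <- unclass(report)
  if (!is.null(ser$overlap_counts)) {
    ser$overlap_counts <- as.list(ser$overlap_counts)
    ser$union_size <- attr(report$overlap_counts, "union_size")
  }
  ser$per_subplex <- lapply(ser$per_subplex, function(x) {
    x$specificity <- unclass(x$specificity); x
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  lines <- c("metric\tscope\tvalue")
  for (sp in names(report$per_subplex)) {
    s <- report$per_subplex[[sp]]
    lines <- c(lines,
      sprintf("frac_zero_missed_cleavage\t%s\t%.6g", sp,
              s$frac_zero_missed_cleavage),
      sprintf("labeling_efficiency_frac\t%s\t%.6g", sp,
              s$labeling_efficiency_frac))
  }
  for (acq in names(report$spike))
    lines <- c(lines,
      sprintf("median_spike_log2\t%s\t%.6g", acq, report$spike[[acq]]$median),
      sprintf("compression_index\t%s\t%.6g", acq,
              report$spike[[acq]]$compression_index))
  writeLines(lines, paste0(path, ".summary.tsv"))
  invisible(path)
}

#' Read a QC report from JSON
#'
#' @param path Path written by [write_qc_report()].
#' @return A [qc_report()]-shaped list.
#' @export
read_qc_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ov <- NULL
  if (!is.null(x$overlap_counts)) {
    ov <- unlist(x$overlap_counts)
    attr(ov, "union_size") <- x$union_size
  }
  per_subplex <- lapply(x$per_subplex, function(s) {
    s$specificity <- structure(as.list(s$specificity),
                               class = "specificity_profile")
    s
  })
  qc_report(per_subplex, overlap = ov, spike = x$spike,
            cv_summaries = x$cv_summaries)
}

# deterministic synthetic protein sequence (composition-weighted residues,
# guaranteed K and R content so both proteases produce peptides)
random_protein_string <- function(len) {
  pool <- names(RESIDUE_MONO_MASS)
  w <- rep(1, 20); names(w) <- pool
  w[c("K", "R")] <- 1.6  # enrich cleavage residues for short test proteins
  paste(sample(pool, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

#' Generate a deterministic fixture set
#'
#' Writes a small, fully synthetic input set sufficient to exercise every
#' pipeline stage end-to-end: a two-species FASTA (synthetic sequences), the
#' reference 58-plex design (JSON + CSV), and simulated MS2-like and
#' MS3-like quant tables. Byte-identical for a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_human,n_ecoli Protein counts (kept small; fixtures are for tests
#'   and documentation, not benchmarks).
#' @return Named list of generated file paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 7L, n_human = 150L, n_ecoli = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  fasta <- file.path(dir, "proteins_synthetic.fasta")
  lines <- character()
  for (i in seq_len(20L)) {
    id <- sprintf("SYNH%03d", i)
    lines <- c(lines, sprintf(">%s synthetic human-like protein %d", id, i),
               random_protein_string(sample(80:200, 1L)))
  }
  for (i in seq_len(10L)) {
    id <- sprintf("SYNE%03d", i)
    lines <- c(lines, sprintf(">%s_ECOLI synthetic spike-in protein %d",
                              id, i),
               random_protein_string(sample(80:200, 1L)))
  }
  writeLines(lines, fasta)

  design <- build_58plex_reference()
  design_json <- file.path(dir, "design_58plex.json")
  design_csv <- file.path(dir, "design_58plex.csv")
  write_design_json(design, design_json)
  write_design_csv(design, design_csv)

  truth <- make_ground_truth(n_human, n_ecoli, seed = seed)
  ms2 <- simulate_quant(design, truth,
                        default_noise_model("MS2", seed = seed), "MS2")
  ms3 <- simulate_quant(design, truth,
                        default_noise_model("MS3", seed = seed), "MS3")
  ms2_path <- file.path(dir, "sim_ms2.tsv")
  ms3_path <- file.path(dir, "sim_ms3.tsv")
  write_quant_tsv(ms2, ms2_path)
  write_quant_tsv(ms3, ms3_path)
  invisible(list(fasta = fasta, design_json = design_json,
                 design_csv = design_csv, ms2 = ms2_path, ms3 = ms3_path))
}
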