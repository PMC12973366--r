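# In silico digestion under LysC / TrypR / TrypKR rules, cleavage-specificity
# classification, labeled-peptide mass computation, and precursor
# orthogonality assessment.

CANONICAL_RESIDUES <- names(RESIDUE_MONO_MASS)

#' Construct a validated protein sequence
#'
#' @param id Accession-like identifier.
#' @param residues Uppercase amino-acid string using only the 20 canonical
#'   letters. Non-canonical letters (B, J, O, U, X, Z, ...) raise an error
#'   naming the first offending position, so that downstream masses are
#'   deterministic.
#' @param species One of `"human"`, `"ecoli"`, `"other"`.
#' @return An object of class `protein_sequence` with fields `id`, `species`,
#'   `residues`.
#' @examples
#' protein_sequence("P1", "MKTAYIAK")
#' @export
protein_sequence <- function(id, residues, species = c("human", "ecoli", "other")) {
  species <- match.arg(species)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  if (!nzchar(residues))
    stop("protein '", id, "': empty sequence", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% CANONICAL_RESIDUES))
  if (length(bad))
    stop("protein '", id, "': non-canonical residue '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  structure(list(id = id, species = species, residues = residues),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s [%s], %d aa\n",
              x$id, x$species, nchar(x$residues)))
  invisible(x)
}

#' Cleavage rules for the orthogonal digestion strategy
#'
#' Three named presets share one cleavage kernel:
#' \describe{
#'   \item{LysC}{cleaves C-terminal to lysine; no proline inhibition.}
#'   \item{TrypR}{trypsin on lysines blocked by prior TMT labeling: nominally
#'     K/R with proline inhibition, but K sites are chemically blocked, so the
#'     net activity is arginine-only.}
#'   \item{TrypKR}{standard proline-inhibited K/R trypsin, used as the QC
#'     search rule to classify specificity of the orthogonal digests.}
#' }
#'
#' @param name One of `"LysC"`, `"TrypR"`, `"TrypKR"`.
#' @return An object of class `cleavage_rule` with fields `name`,
#'   `cleave_after`, `proline_inhibited`, `blocked_residues`.
#' @examples
#' cleavage_rule("TrypR")
#' @export
cleavage_rule <- function(name = c("LysC", "TrypR", "TrypKR")) {
  name <- match.arg(name)
  rule <- switch(name,
    LysC   = list(cleave_after = "K",        proline_inhibited = FALSE,
                  blocked_residues = character()),
    TrypR  = list(cleave_after = c("K", "R"), proline_inhibited = TRUE,
                  blocked_residues = "K"),
    TrypKR = list(cleave_after = c("K", "R"), proline_inhibited = TRUE,
                  blocked_residues = character())
  )
  structure(c(list(name = name), rule), class = "cleavage_rule")
}

# 1-based indices of residues after which the rule cleaves. Cleavage after the
# final residue is the protein C-terminus and produces no internal boundary.
active_cleavage_sites <- function(residues, rule) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer())
  idx <- seq_len(n - 1L)
  ok <- chars[idx] %in% rule$cleave_after &
    !(chars[idx] %in% rule$blocked_residues)
  if (rule$proline_inhibited)
    ok <- ok & chars[idx + 1L] != "P"
  idx[ok]
}

#' Digest a protein in silico
#'
#' Enumerates every peptide bounded by active cleavage sites of `rule` with at
#' most `max_missed` internal (missed) sites. An active site is a residue in
#' the rule's cleave-after set that is not chemically blocked and, for
#' proline-inhibited rules, not immediately followed by P. Protein N- and
#' C-terminal peptides are included; output is sorted by (start, end).
#'
#' @param protein A [protein_sequence()].
#' @param rule A [cleavage_rule()] or its name.
#' @param max_missed Maximum number of missed cleavages (default 2, the usual
#'   search-engine setting).
#' @return A `data.frame` with one row per peptide: `protein_id`, `start`,
#'   `end` (0-based half-open coordinates into the parent; see
#'   [coords_to_one_based()]), `sequence`, `missed_cleavages`,
#'   `n_term_is_protein_n_term`, `c_term_is_protein_c_term`, `rule`.
#' @examples
#' digest(protein_sequence("toy", "AKEKR"), "LysC", max_missed = 0)$sequence
#' @export
digest <- function(protein, rule, max_missed = 2L) {
  if (is.character(rule)) rule <- cleavage_rule(rule)
  stopifnot(inherits(protein, "protein_sequence"),
            inherits(rule, "cleavage_rule"))
  if (max_missed < 0L) stop("max_missed must be >= 0", call. = FALSE)
  n <- nchar(protein$residues)
  boundaries <- c(0L, active_cleavage_sites(protein$residues, rule), n)
  nb <- length(boundaries)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    j <- (i + 1L):jmax
    out[[i]] <- data.frame(
      protein_id = protein$id,
      start = boundaries[i],
      end = boundaries[j],
      missed_cleavages = j - i - 1L,
      stringsAsFactors = FALSE
    )
  }
  pep <- do.call(rbind, out)
  pep$sequence <- substring(protein$residues, pep$start + 1L, pep$end)
  pep$n_term_is_protein_n_term <- pep$start == 0L
  pep$c_term_is_protein_c_term <- pep$end == n
  pep$rule <- rule$name
  pep <- pep[order(pep$start, pep$end),
             c("protein_id", "start", "end", "sequence", "missed_cleavages",
               "n_term_is_protein_n_term", "c_term_is_protein_c_term", "rule")]
  rownames(pep) <- NULL
  pep
}

#' Digest many proteins
#'
#' @param proteins List of [protein_sequence()] objects.
#' @inheritParams digest
#' @return Row-bound peptide `data.frame` (see [digest()]).
#' @export
digest_all <- function(proteins, rule, max_missed = 2L) {
  do.call(rbind, lapply(proteins, digest, rule = rule, max_missed = max_missed))
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' @param start,end 0-based half-open coordinates.
#' @return A list with 1-based inclusive `first` and `last`.
#' @export
coords_to_one_based <- function(start, end) {
  list(first = start + 1L, last = end)
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' @param first,last 1-based inclusive coordinates.
#' @return A list with 0-based half-open `start` and `end`.
#' @export
coords_to_zero_based <- function(first, last) {
  list(start = first - 1L, end = last)
}

#' Count lysine- and arginine-attributable cleavage events in a peptide
#'
#' An event is the peptide's C-terminal residue (when it is not the protein
#' C-terminus) plus every internal K or R not immediately followed by P
#' (the proline-inhibited trypsin convention used by the QC search).
#' Over a peptide collection these counts drive the specificity profile:
#' lysine-specific peptides have zero R events; arginine-specific peptides
#' have zero K events.
#'
#' @param peptide One row of a [digest()] data.frame (or any list with
#'   `sequence`, `start`, `end`, `c_term_is_protein_c_term`).
#' @param parent Optional [protein_sequence()]; when supplied the peptide is
#'   checked to be the substring at its stated coordinates.
#' @return Integer vector `c(k_events = , r_events = )`.
#' @examples
#' p <- list(sequence = "ARAEK", start = 0L, end = 5L,
#'           c_term_is_protein_c_term = FALSE)
#' classify_cleavage_events(p)
#' @export
classify_cleavage_events <- function(peptide, parent = NULL) {
  seqc <- peptide$sequence
  if (!is.null(parent)) {
    ref <- substring(parent$residues, peptide$start + 1L, peptide$end)
    if (!identical(ref, seqc))
      stop("peptide '", seqc, "' is not the parent substring at [",
           peptide$start, ", ", peptide$end, ")", call. = FALSE)
  }
  chars <- strsplit(seqc, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  k <- 0L; r <- 0L
  if (n > 1L) {
    internal <- seq_len(n - 1L)
    hit <- chars[internal] %in% c("K", "R") & chars[internal + 1L] != "P"
    k <- sum(chars[internal] == "K" & hit)
    r <- sum(chars[internal] == "R" & hit)
  }
  if (!isTRUE(peptide$c_term_is_protein_c_term)) {
    if (chars[n] == "K") k <- k + 1L
    if (chars[n] == "R") r <- r + 1L
  }
  c(k_events = k, r_events = r)
}

#' Cleavage-specificity profile of a peptide collection
#'
#' Classifies each peptide by its K- and R-attributable cleavage events
#' (see [classify_cleavage_events()]) and reports the unweighted fractions
#' used to QC the orthogonal digestion strategy: lysine-specific peptides
#' (no R events) should dominate a LysC digest, arginine-specific peptides
#' (no K events) a TrypR digest, and the two-site categories flag potential
#' cross-digest interference.
#'
#' @param peptides A [digest()]-style data.frame.
#' @return A list of class `specificity_profile`: `n_peptides`,
#'   `frac_lysine_specific`, `frac_one_arginine`, `frac_two_arginine`,
#'   `frac_arginine_specific`, `frac_two_lysine`.
#' @export
specificity_profile <- function(peptides) {
  if (!is.data.frame(peptides) || nrow(peptides) == 0L)
    stop("need a non-empty peptide data.frame", call. = FALSE)
  ev <- t(vapply(seq_len(nrow(peptides)), function(i)
    classify_cleavage_events(peptides[i, ]), integer(2L)))
  n <- nrow(ev)
  structure(list(
    n_peptides = n,
    frac_lysine_specific   = sum(ev[, "r_events"] == 0L) / n,
    frac_one_arginine      = sum(ev[, "r_events"] == 1L) / n,
    frac_two_arginine      = sum(ev[, "r_events"] >= 2L) / n,
    frac_arginine_specific = sum(ev[, "k_events"] == 0L) / n,
    frac_two_lysine        = sum(ev[, "k_events"] >= 2L) / n
  ), class = "specificity_profile")
}

#' Monoisotopic neutral mass of a (possibly modified) peptide
#'
#' Neutral mass = sum of residue masses + water + sum of modification deltas.
#' Each applied modification names its site: `"N-term"` or a 1-based residue
#' position whose residue must be in the modification's target set.
#'
#' @param peptide A peptide row (list with `sequence`) or a plain sequence
#'   string.
#' @param mods List of applied modifications, each a list with `spec`
#'   (a [modification_spec()]) and `site` (`"N-term"` or 1-based position).
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' peptide_neutral_mass("AK")  # 217.14264
#' tmt <- modification_registry()$TMTpro
#' peptide_neutral_mass("AK", list(list(spec = tmt, site = "N-term"),
#'                                 list(spec = tmt, site = 2)))
#' @export
peptide_neutral_mass <- function(peptide, mods = list()) {
  seqc <- if (is.character(peptide)) peptide else peptide$sequence
  chars <- strsplit(seqc, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% CANONICAL_RESIDUES))
  if (length(bad))
    stop("non-canonical residue '", chars[bad[1L]], "' at position ",
         bad[1L], call. = FALSE)
  mass <- sum(RESIDUE_MONO_MASS[chars]) + WATER_MASS
  for (m in mods) {
    spec <- m$spec; site <- m$site
    if (identical(site, "N-term")) {
      if (!("N-term" %in% spec$targets))
        stop("modification '", spec$name, "' does not target the N-terminus",
             call. = FALSE)
    } else {
      site <- as.integer(site)
      if (site < 1L || site > length(chars))
        stop("modification '", spec$name, "' targets absent position ", site,
             call. = FALSE)
      if (!(chars[site] %in% spec$targets))
        stop("modification '", spec$name, "' does not target residue '",
             chars[site], "' at position ", site, call. = FALSE)
    }
    mass <- mass + spec$delta_mass
  }
  mass
}

#' Apply a fixed modification at every eligible site of a peptide
#'
#' Eligible sites are the N-terminus (if targeted) plus every residue in the
#' modification's target set. This is how amine-reactive isobaric labels
#' (N-term + K) are applied in bulk.
#'
#' @param sequence Peptide sequence string.
#' @param spec A [modification_spec()].
#' @return List with `n_sites` (count of eligible sites) and `mods` (the
#'   applied-modification list accepted by [peptide_neutral_mass()]).
#' @export
apply_fixed_modification <- function(sequence, spec) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mods <- list()
  if ("N-term" %in% spec$targets)
    mods[[length(mods) + 1L]] <- list(spec = spec, site = "N-term")
  for (i in which(chars %in% spec$targets))
    mods[[length(mods) + 1L]] <- list(spec = spec, site = i)
  list(n_sites = length(mods), mods = mods)
}

#' Mass-to-charge ratio of a peptide ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z = (mass + charge * proton mass) / charge.
#' @examples
#' ion_mz(1000, 2)  # 500.503638
#' @export
ion_mz <- function(mass, charge) {
  if (any(charge < 1L)) stop("charge must be >= 1", call. = FALSE)
  (mass + charge * PROTON_MASS) / charge
}

#' Build a charge-resolved ion list from a peptide table
#'
#' Computes the labeled monoisotopic mass of every peptide (isobaric label at
#' N-terminus and each K, by default TMTpro) and expands it over the given
#' charge states. The default charges \{2, 3, 4\} reflect the charge
#' distribution observed for LysC/TrypR peptides.
#'
#' @param peptides A [digest()]-style data.frame.
#' @param label A [modification_spec()] applied at every eligible site, or
#'   `NULL` for unlabeled masses.
#' @param charges Integer vector of charge states.
#' @return `peptides` expanded over charges, with columns `charge`, `mz` and
#'   `neutral_mass` added.
#' @export
peptide_ions <- function(peptides, label = modification_registry()$TMTpro,
                         charges = c(2L, 3L, 4L)) {
  stopifnot(is.data.frame(peptides), nrow(peptides) > 0L, all(charges >= 1L))
  mass <- vapply(peptides$sequence, function(s) {
    mods <- if (is.null(label)) list() else apply_fixed_modification(s, label)$mods
    peptide_neutral_mass(s, mods)
  }, numeric(1L), USE.NAMES = FALSE)
  out <- peptides[rep(seq_len(nrow(peptides)), each = length(charges)), ,
                  drop = FALSE]
  out$neutral_mass <- rep(mass, each = length(charges))
  out$charge <- rep(as.integer(charges), times = nrow(peptides))
  out$mz <- ion_mz(out$neutral_mass, out$charge)
  rownames(out) <- NULL
  out
}

#' Precursor-level orthogonality between two ion populations
#'
#' Fraction of ions in `a` whose m/z lies within `tol_ppm` of at least one ion
#' in `b`, and the symmetric fraction of `b` near `a`. Orthogonal digests
#' should give fractions near zero; identical digests give 1. The default
#' tolerance of 10 ppm mirrors a typical precursor/dynamic-exclusion mass
#' tolerance.
#'
#' @param ions_a,ions_b Numeric m/z vectors, or data.frames with an `mz`
#'   column (as returned by [peptide_ions()]).
#' @param tol_ppm Matching tolerance in parts per million (> 0).
#' @return Named numeric vector `c(frac_a_in_b = , frac_b_in_a = )`.
#' @export
precursor_orthogonality <- function(ions_a, ions_b, tol_ppm = 10) {
  mz_a <- if (is.data.frame(ions_a)) ions_a$mz else ions_a
  mz_b <- if (is.data.frame(ions_b)) ions_b$mz else ions_b
  if (length(mz_a) == 0L || length(mz_b) == 0L)
    stop("ion lists must be non-empty", call. = FALSE)
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  frac_near <- function(x, ref) {
    ref <- sort(ref)
    tol <- x * tol_ppm * 1e-6
    lo <- findInterval(x - tol, ref)
    hi <- findInterval(x + tol, ref)
    mean(hi > lo)
  }
  c(frac_a_in_b = frac_near(mz_a, mz_b),
    frac_b_in_a = frac_near(mz_b, mz_a))
}
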