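# Independent oracles used by the property-style tests. These deliberately
# use naive enumeration so they share no code path with the implementation.

random_sequence <- function(len) {
  paste(sample(names(ultraplex::RESIDUE_MONO_MASS), len, replace = TRUE),
        collapse = "")
}

# O(n^2) digestion oracle: enumerate every substring, keep those whose
# endpoints are active boundaries and whose internal active-site count is
# within the missed-cleavage budget.
brute_force_digest <- function(residues, rule_name, max_missed) {
  rule <- ultraplex::cleavage_rule(rule_name)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_site <- vapply(seq_len(n - 1), function(i) {
    chars[i] %in% rule$cleave_after &&
      !(chars[i] %in% rule$blocked_residues) &&
      !(rule$proline_inhibited && chars[i + 1] == "P")
  }, logical(1))
  boundaries <- c(0, which(is_site), n)
  out <- list()
  for (s in 0:(n - 1)) for (e in (s + 1):n) {
    if (!(s %in% boundaries) || !(e %in% boundaries)) next
    internal <- if (e - s >= 2) sum(is_site[(s + 1):(e - 1)]) else 0
    if (internal <= max_missed)
      out[[length(out) + 1]] <- data.frame(
        start = s, end = e,
        sequence = substr(residues, s + 1, e),
        missed_cleavages = internal)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), ]
  rownames(res) <- NULL
  res
}

# all-pairs orthogonality oracle
brute_force_overlap_fraction <- function(mz_a, mz_b, tol_ppm) {
  hit <- vapply(mz_a, function(x)
    any(abs(x - mz_b) <= tol_ppm * 1e-6 * x), logical(1))
  mean(hit)
}

# set-algebra Venn oracle: each region via intersect/setdiff, independent of
# the membership-vector tally in overlap_counts()
brute_force_venn <- function(sets) {
  nm <- names(sets)
  out <- integer(0)
  for (mask in 1:15) {
    inn <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1)) > 0]
    outn <- setdiff(nm, inn)
    region <- Reduce(intersect, sets[inn])
    for (o in outn) region <- setdiff(region, sets[[o]])
    out[paste(inn, collapse = "&")] <- length(region)
  }
  out
}

# small raw quant table built by hand for normalization unit tests
toy_quant_table <- function(values, species = NULL, subplexes = NULL) {
  if (is.null(species))
    species <- stats::setNames(rep("human", nrow(values)), rownames(values))
  if (is.null(subplexes))
    subplexes <- rep("S1", ncol(values))
  channels <- sub("^.*\\|", "", colnames(values))
  ultraplex::quant_table(
    values, species,
    data.frame(column = colnames(values), subplex = subplexes,
               channel = channels, stringsAsFactors = FALSE))
}
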