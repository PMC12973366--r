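# Plex-design construction and validation: protease x tag-set subplexes,
# channel -> sample assignment, bridge channels, E. coli spike layout, and
# multiplexing-capacity arithmetic.

#' Isobaric tag sets
#'
#' Channel label lists for the supported reagent sets. TMT11 holds 11 channels
#' (126..131C); TMTpro18 holds 18 (126..135N), of which \{132N, 132C, 133N,
#' 133C, 134N, 134C, 135N\} are unique relative to TMT11. The 35-plex set is
#' represented by synthetic channel labels (`ch01`..`ch35`): only its size
#' enters capacity arithmetic.
#'
#' @param name One of `"TMT11"`, `"TMTpro18"`, `"TMTpro35"`.
#' @return An object of class `tag_set` with fields `name`, `channels`,
#'   `size`.
#' @examples
#' tag_set("TMT11")$size
#' @export
tag_set <- function(name = c("TMT11", "TMTpro18", "TMTpro35")) {
  name <- match.arg(name)
  channels <- switch(name,
    TMT11 = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
              "130N", "130C", "131N", "131C"),
    TMTpro18 = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                 "130N", "130C", "131N", "131C", "132N", "132C", "133N",
                 "133C", "134N", "134C", "135N"),
    TMTpro35 = sprintf("ch%02d", 1:35)
  )
  structure(list(name = name, channels = channels,
                 size = length(channels)), class = "tag_set")
}

#' Construct a subplex
#'
#' One protease x tag-set unit of an UltraPlex design: a channel-to-sample
#' assignment, the bridge channels carrying the common reference sample, and
#' the per-channel E. coli spike amount (micrograms).
#'
#' @param id Unique subplex identifier (e.g. `"LysC-TMT11"`).
#' @param protease Cleavage-rule name (`"LysC"` or `"TrypR"`).
#' @param tags A [tag_set()] or its name.
#' @param assignments Named character vector channel -> sample label; unused
#'   channels carry the label `"UNUSED"`.
#' @param bridge_channels Channel labels holding the bridge sample.
#' @param spike_ug Named numeric vector channel -> E. coli spike (micrograms);
#'   required for every assigned (non-UNUSED) channel.
#' @return An object of class `subplex`.
#' @export
subplex <- function(id, protease, tags, assignments, bridge_channels,
                    spike_ug) {
  if (is.character(tags)) tags <- tag_set(tags)
  stopifnot(inherits(tags, "tag_set"),
            !is.null(names(assignments)), !is.null(names(spike_ug)))
  structure(list(id = id, protease = protease, tag_set = tags,
                 assignments = assignments,
                 bridge_channels = bridge_channels,
                 spike_ug = spike_ug),
            class = "subplex")
}

assigned_channels <- function(sp) {
  names(sp$assignments)[sp$assignments != "UNUSED"]
}

#' Construct a plex design
#'
#' @param subplexes List of [subplex()] objects with unique ids.
#' @param cell_lines Character vector of biological sample labels.
#' @return An object of class `plex_design`.
#' @export
plex_design <- function(subplexes, cell_lines) {
  ids <- vapply(subplexes, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("subplex ids must be unique", call. = FALSE)
  structure(list(subplexes = subplexes, cell_lines = cell_lines),
            class = "plex_design")
}

#' @export
print.plex_design <- function(x, ...) {
  cat(sprintf("<plex_design> %d subplexes, %d assigned channels\n",
              length(x$subplexes),
              sum(vapply(x$subplexes,
                         function(s) length(assigned_channels(s)), 0L))))
  for (sp in x$subplexes)
    cat(sprintf("  %s: %s x %s, %d channels (%d bridge)\n", sp$id,
                sp$protease, sp$tag_set$name,
                length(assigned_channels(sp)), length(sp$bridge_channels)))
  invisible(x)
}

#' Multiplexing capacity of a hyperplexed design
#'
#' Sample capacity = number of proteases x number of peptide-barcode states x
#' sum of tag-set sizes. The dual-protease TMT11+TMTpro18 layout gives
#' 2 x (11 + 18) = 58 channels; swapping the 18-plex for a 35-plex reagent
#' gives 92; a dual-protease 35-plex layout with a three-state peptide
#' barcode reaches 210.
#'
#' @param n_proteases Number of orthogonal proteases (>= 1).
#' @param tag_set_sizes Integer vector of tag-set sizes combined per protease.
#' @param n_barcode_states Number of peptide-barcoding states (1 = none).
#' @return Integer sample capacity.
#' @examples
#' capacity(2, c(11, 18))      # 58
#' capacity(2, c(35), 3)       # 210
#' @export
capacity <- function(n_proteases, tag_set_sizes, n_barcode_states = 1L) {
  if (n_proteases < 1L || n_barcode_states < 1L ||
      length(tag_set_sizes) < 1L || any(tag_set_sizes < 1L))
    stop("all capacity arguments must be >= 1", call. = FALSE)
  as.integer(n_proteases) * as.integer(n_barcode_states) *
    sum(as.integer(tag_set_sizes))
}

#' Build the reference pseudo-58-plex design
#'
#' Four subplexes (LysC-TMT11, LysC-TMT18, TrypR-TMT11, TrypR-TMT18), each
#' carrying the common bridge sample in the same four reporter channels
#' (126, 127N, 127C, 128N). The four cell lines fill the remaining channels
#' in a balanced round-robin layout, and every channel receives an E. coli
#' spike of `spike_high` or `spike_low` micrograms in an alternating balanced
#' layout (defaults 1.0 and 0.5, i.e. expected spike log2 ratio of 1). The
#' per-channel cell-line layout is a documented reference layout, not a
#' facsimile of any particular bench run.
#'
#' @param cell_lines Exactly four distinct sample labels.
#' @param spike_high,spike_low E. coli spike amounts in micrograms;
#'   `spike_high > spike_low > 0`.
#' @return A validated [plex_design()] with 58 assigned channels.
#' @examples
#' d <- build_58plex_reference()
#' length(validate_design(d))  # 0
#' @export
build_58plex_reference <- function(cell_lines = c("HT55", "LS1034",
                                                  "MDST8", "SW948"),
                                   spike_high = 1.0, spike_low = 0.5) {
  if (length(cell_lines) != 4L || anyDuplicated(cell_lines))
    stop("need exactly 4 distinct cell-line labels", call. = FALSE)
  if (!(spike_high > spike_low && spike_low > 0))
    stop("need spike_high > spike_low > 0", call. = FALSE)
  bridge <- c("126", "127N", "127C", "128N")
  specs <- list(
    list(id = "LysC-TMT11",  protease = "LysC",  tags = "TMT11"),
    list(id = "LysC-TMT18",  protease = "LysC",  tags = "TMTpro18"),
    list(id = "TrypR-TMT11", protease = "TrypR", tags = "TMT11"),
    list(id = "TrypR-TMT18", protease = "TrypR", tags = "TMTpro18")
  )
  subplexes <- vector("list", length(specs))
  cl_cursor <- 0L  # global round-robin so each cell line appears 10-11 times
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    ts <- tag_set(s$tags)
    assignments <- stats::setNames(rep("BRIDGE", ts$size), ts$channels)
    nonbridge <- setdiff(ts$channels, bridge)
    for (ch in nonbridge) {
      assignments[ch] <- cell_lines[cl_cursor %% 4L + 1L]
      cl_cursor <- cl_cursor + 1L
    }
    # the bridge sample is one physical pool shared by all subplexes, so its
    # spike amount is fixed (high); non-bridge channels alternate high/low,
    # offset per subplex so the layout is balanced across the design
    spike_ug <- stats::setNames(rep(spike_high, ts$size), ts$channels)
    spike_ug[nonbridge] <-
      ifelse((seq_along(nonbridge) + i) %% 2L == 0L, spike_high, spike_low)
    subplexes[[i]] <- subplex(s$id, s$protease, ts, assignments, bridge,
                              spike_ug)
  }
  plex_design(subplexes, cell_lines)
}

#' Validate a plex design
#'
#' Checks (returning violations, not raising): bridge channels occupy
#' identical reporter labels in every subplex; bridge labels exist in each
#' subplex's tag set; assigned channels belong to the tag set; every assigned
#' channel has a positive spike amount; no sample label repeats within a
#' subplex's non-bridge channels (repeats are reported as replicate notes
#' only when `allow_replicates` is TRUE).
#'
#' @param design A [plex_design()].
#' @param allow_replicates Logical; when TRUE, repeated non-bridge sample
#'   labels within a subplex are not violations (the reference design uses
#'   balanced replicates of four cell lines).
#' @return Character vector of violations; empty if the design is valid.
#' @export
validate_design <- function(design, allow_replicates = TRUE) {
  v <- character()
  bridges <- lapply(design$subplexes, `[[`, "bridge_channels")
  ref_bridge <- bridges[[1L]]
  for (sp in design$subplexes) {
    if (!identical(sort(sp$bridge_channels), sort(ref_bridge)))
      v <- c(v, sprintf("subplex %s: bridge channels differ from %s",
                        sp$id, design$subplexes[[1L]]$id))
    missing_bridge <- setdiff(sp$bridge_channels, sp$tag_set$channels)
    if (length(missing_bridge))
      v <- c(v, sprintf("subplex %s: bridge channel(s) %s not in tag set %s",
                        sp$id, paste(missing_bridge, collapse = ","),
                        sp$tag_set$name))
    bad_ch <- setdiff(names(sp$assignments), sp$tag_set$channels)
    if (length(bad_ch))
      v <- c(v, sprintf("subplex %s: channel(s) %s not in tag set %s",
                        sp$id, paste(bad_ch, collapse = ","),
                        sp$tag_set$name))
    ac <- assigned_channels(sp)
    no_spike <- ac[!(ac %in% names(sp$spike_ug)) |
                     !is.finite(sp$spike_ug[ac]) | sp$spike_ug[ac] <= 0]
    no_spike <- no_spike[!is.na(no_spike)]
    if (length(no_spike))
      v <- c(v, sprintf("subplex %s: assigned channel(s) %s lack a positive spike amount",
                        sp$id, paste(no_spike, collapse = ",")))
    if (!allow_replicates) {
      nb <- setdiff(ac, sp$bridge_channels)
      labs <- sp$assignments[nb]
      dup <- unique(labs[duplicated(labs)])
      if (length(dup))
        v <- c(v, sprintf("subplex %s: sample label(s) %s repeated in non-bridge channels",
                          sp$id, paste(dup, collapse = ",")))
    }
  }
  v
}

#' Expected spike log2 ratios between channel pairs
#'
#' For each subplex, log2(spike_a / spike_b) for every ordered pair of
#' assigned channels. With the default 1.0 vs 0.5 microgram spikes, high/low
#' pairs have expected log2 ratio 1.
#'
#' @param design A validated [plex_design()].
#' @return A `data.frame` with columns `subplex`, `channel_a`, `channel_b`,
#'   `expected_log2`.
#' @export
expected_ratio_matrix <- function(design) {
  out <- list()
  for (sp in design$subplexes) {
    ac <- assigned_channels(sp)
    sp_amt <- sp$spike_ug[ac]
    if (any(sp_amt <= 0))
      stop("subplex ", sp$id, ": zero spike amount", call. = FALSE)
    grid <- expand.grid(channel_a = ac, channel_b = ac,
                        stringsAsFactors = FALSE)
    grid$subplex <- sp$id
    grid$expected_log2 <- log2(sp_amt[grid$channel_a] / sp_amt[grid$channel_b])
    out[[sp$id]] <- grid[, c("subplex", "channel_a", "channel_b",
                             "expected_log2")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
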