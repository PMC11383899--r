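# Small constructed fixtures for migration tests: a well-table builder
# that emits the read_wells() schema with exact (noise-free) counts so
# expected calls can be derived by hand. bead_events == beads_added, so
# bead arithmetic is the identity.

make_wells <- function(rows, subsets = c("cDC1", "cDC2")) {
  out <- NULL
  wid <- 0
  for (r in rows) {
    for (i in seq_along(r$counts[[1]])) {
      wid <- wid + 1
      row <- data.frame(
        well_id = sprintf("W%03d", wid),
        attractant_id = r$attractant_id,
        attractant_class = r$class,
        donor_id = r$donor,
        replicate = i,
        bead_events = 10000,
        beads_added = 10000,
        stringsAsFactors = FALSE)
      for (s in subsets) {
        row[[s]] <- if (s %in% names(r$counts)) r$counts[[s]][i] else 0
      }
      out <- rbind(out, row)
    }
  }
  out
}

well_row <- function(attractant_id, class, donor, counts) {
  list(attractant_id = attractant_id, class = class, donor = donor,
       counts = counts)
}

# A minimal complete experiment for one donor: negative control at
# `neg`, positive control at `pos`, plus the supplied attractants.
donor_block <- function(donor, neg, pos, attractants = list(),
                        subsets = c("cDC1", "cDC2")) {
  reps <- function(v) {
    if (is.list(v)) v else stats::setNames(
      lapply(subsets, function(s) v), subsets)
  }
  c(list(well_row("NEG", "negative_control", donor, reps(neg)),
         well_row("POS", "positive_control", donor, reps(pos))),
    attractants)
}
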