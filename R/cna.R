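#' Estimate probe-level copy numbers against a reference pool
#'
#' `copies = baseline * tumor / reference` per probe, with baseline 2 on
#' autosomes and sex-adjusted on X/Y (male X = Y = 1; female X = 2).
#' Y probes of female samples are excluded (set NA) with a logged count.
#'
#' @param tumor probe x sample matrix of tumor intensities.
#' @param reference per-probe reference-pool intensities (strictly positive),
#'   length nrow(tumor).
#' @param probes data.frame probe_id, chromosome, position matching rows.
#' @param samples sample sheet covering the columns (for sex baselines).
#' @return `copy_profiles`.
#' @export
estimate_copies <- function(tumor, reference, probes, samples) {
  if (nrow(tumor) != nrow(probes) || nrow(tumor) != length(reference)) {
    stop("probe-set mismatch between tumor, reference and probe table")
  }
  if (any(reference <= 0)) stop("reference intensities must be strictly positive")
  sex <- samples$sex[match(colnames(tumor), samples$sample_id)]
  if (any(is.na(sex))) stop("samples missing from sheet: ",
                            paste(colnames(tumor)[is.na(sex)], collapse = ", "))
  ratio <- tumor / reference
  copies <- matrix(NA_real_, nrow(tumor), ncol(tumor),
                   dimnames = dimnames(tumor))
  n_excluded <- 0L
  for (j in seq_len(ncol(tumor))) {
    base <- baseline_copies(probes$chromosome, sex[j])
    copies[, j] <- base * ratio[, j]
    n_excluded <- n_excluded + sum(is.na(base))
  }
  if (n_excluded > 0) {
    message(n_excluded, " female Y probe value(s) excluded from copy estimation")
  }
  cp <- copy_profiles(probes, copies)
  attr(cp, "n_excluded_female_y") <- n_excluded
  cp
}

# Default segmentation penalty: 2 * sigma^2 * log(n), with the noise
# variance estimated from first differences (robust to true level shifts
# when changepoints are sparse).
default_penalty <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sigma2 <- sum(diff(x)^2) / (2 * (n - 1))
  2 * sigma2 * log(n)
}

#' Exact penalized least-squares changepoint segmentation
#'
#' Minimizes sum of within-segment squared errors plus `penalty` per
#' segment by exact dynamic programming (O(n^2)); ties are broken toward
#' fewer segments. Segments must hold at least `min_size` probes (relaxed
#' to the profile length when the profile is shorter).
#'
#' @param x numeric copy values for one sample on one chromosome,
#'   position-sorted.
#' @param positions optional probe positions (must be strictly increasing).
#' @param penalty per-segment penalty; default `2 * sigma^2 * log(n)` with
#'   sigma estimated from first differences.
#' @param min_size minimum probes per segment (default 3).
#' @return data.frame: start_idx, end_idx, n_probes, mean_copies (plus
#'   start/end positions when `positions` given).
#' @export
segment_profile <- function(x, positions = NULL, penalty = NULL, min_size = 3) {
  n <- length(x)
  if (n < 1) stop("empty profile")
  if (!is.null(positions)) {
    if (length(positions) != n) stop("positions length mismatch")
    if (n > 1 && any(diff(positions) <= 0)) stop("probes not position-sorted")
  }
  if (is.null(penalty)) penalty <- default_penalty(x)
  m <- min(min_size, n)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) {  # probes i..j, 1-based inclusive
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  F <- rep(Inf, n + 1)  # F[j+1] = best cost of probes 1..j
  F[1] <- 0
  back <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < m) next
    best <- Inf; arg <- NA_integer_
    for (i in seq(0, j - m)) {          # previous boundary after probe i
      if (i > 0 && i < m) next          # first segment must reach min size
      if (!is.finite(F[i + 1])) next
      cost <- F[i + 1] + sse(i + 1, j) + penalty
      if (cost < best - 1e-12) { best <- cost; arg <- i }
    }
    F[j + 1] <- best
    back[j + 1] <- arg
  }
  if (!is.finite(F[n + 1])) {  # profile shorter than min size handled by m, so this is defensive
    stop("no feasible segmentation")
  }
  bounds <- integer(0)
  j <- n
  while (j > 0) {
    i <- back[j + 1]
    bounds <- c(i + 1, bounds)
    j <- i
  }
  starts <- bounds
  ends <- c(bounds[-1] - 1, n)
  out <- data.frame(start_idx = starts, end_idx = ends,
                    n_probes = ends - starts + 1,
                    mean_copies = vapply(seq_along(starts), function(k) {
                      mean(x[starts[k]:ends[k]])
                    }, numeric(1)))
  if (!is.null(positions)) {
    out$start <- positions[starts]
    out$end <- positions[ends]
  }
  out
}

#' Segment all samples and chromosomes of a copy-number set
#'
#' Runs [segment_profile()] per sample x chromosome and assembles a
#' genome-wide segment table with sex-appropriate baselines and arm labels
#' (a segment spanning the centromere is labeled `"pq"` and counts toward
#' both arms).
#'
#' @param cp `copy_profiles`.
#' @param samples sample sheet (for sex baselines).
#' @param penalty per-segment penalty, or NULL for the per-profile default.
#' @param min_size minimum probes per segment.
#' @param geometry chromosome geometry for arm labels.
#' @return segment data.frame: sample_id, chromosome, arm_label, start, end,
#'   n_probes, mean_copies, baseline.
#' @export
segment_profiles <- function(cp, samples, penalty = NULL, min_size = 3,
                             geometry = chrom_geometry()) {
  sex <- samples$sex[match(colnames(cp$copies), samples$sample_id)]
  if (any(is.na(sex))) stop("samples missing from sheet")
  pieces <- list()
  for (j in seq_len(ncol(cp$copies))) {
    sid <- colnames(cp$copies)[j]
    for (chr in unique(cp$probes$chromosome)) {
      idx <- which(cp$probes$chromosome == chr)
      x <- cp$copies[idx, j]
      keep <- !is.na(x)
      if (!any(keep)) next   # e.g. female Y
      x <- x[keep]
      pos <- cp$probes$position[idx][keep]
      seg <- segment_profile(x, pos, penalty = penalty, min_size = min_size)
      cen <- geometry$centromere_mb[match(chr, geometry$chromosome)] * 1e6
      arm <- ifelse(seg$end <= cen, "p", ifelse(seg$start > cen, "q", "pq"))
      pieces[[length(pieces) + 1]] <- data.frame(
        sample_id = sid, chromosome = chr, arm_label = arm,
        start = seg$start, end = seg$end, n_probes = seg$n_probes,
        mean_copies = seg$mean_copies,
        baseline = baseline_copies(chr, sex[j]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, pieces)
}

#' Call gains and losses on segments with fixed cutoffs
#'
#' On autosomes a segment is a gain iff `mean_copies > 2.7` and a loss iff
#' `mean_copies < 1.3` (strict inequalities; the boundary is neutral).
#' On sex chromosomes the cutoffs are scaled by `baseline / 2` (e.g. male X
#' gain above 1.35).
#'
#' @param segments segment data.frame with `mean_copies` and `baseline`.
#' @param gain_cutoff gain threshold at baseline 2 (default 2.7).
#' @param loss_cutoff loss threshold at baseline 2 (default 1.3).
#' @return segments with a `call` column (`gain`/`loss`/`neutral`).
#' @export
call_segments <- function(segments, gain_cutoff = 2.7, loss_cutoff = 1.3) {
  if (loss_cutoff >= 2 || gain_cutoff <= 2 || loss_cutoff >= gain_cutoff) {
    stop("cutoffs must satisfy loss < baseline(2) < gain")
  }
  scale <- segments$baseline / 2
  call <- rep("neutral", nrow(segments))
  call[segments$mean_copies > gain_cutoff * scale] <- "gain"
  call[segments$mean_copies < loss_cutoff * scale] <- "loss"
  segments$call <- call
  segments
}

#' Convert called segments to per-sample gain/loss events
#'
#' One event row per (sample, chromosome, arm, call) for non-neutral
#' segments; centromere-spanning segments contribute to both arms.
#'
#' @param segments called segment data.frame.
#' @return data.frame: sample_id, chromosome, arm (p/q), event.
#' @export
segments_to_events <- function(segments) {
  s <- segments[segments$call %in% c("gain", "loss"), , drop = FALSE]
  if (!nrow(s)) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      arm = character(), event = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (i in seq_len(nrow(s))) {
    arms <- if (s$arm_label[i] == "pq") c("p", "q") else s$arm_label[i]
    for (a in arms) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s$sample_id[i], chromosome = s$chromosome[i],
        arm = a, event = s$call[i], stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, rows))
}

#' Parse whole-chromosome / arm event tokens into an event table
#'
#' Tokens such as `"19p"`, `"11"`, `"5q"` (as printed in per-tumor
#' gain/loss lists) become event rows; a bare chromosome token means a
#' whole-chromosome event (arm NA, matching either arm).
#'
#' @param sample_id sample the tokens belong to.
#' @param tokens character vector of tokens (may be empty).
#' @param event `"gain"` or `"loss"`.
#' @return event data.frame: sample_id, chromosome, arm, event.
#' @export
parse_event_tokens <- function(sample_id, tokens, event) {
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      arm = character(), event = character(),
                      stringsAsFactors = FALSE))
  }
  arm <- ifelse(grepl("[pq]$", tokens), substring(tokens, nchar(tokens)), NA)
  chrom <- normalize_chrom(sub("[pq]$", "", tokens))
  data.frame(sample_id = sample_id, chromosome = chrom, arm = arm,
             event = event, stringsAsFactors = FALSE)
}

# does an event row match a queried chromosome (+ optional arm)?
# Whole-chromosome events (arm NA) match both arm- and chromosome-level
# queries; arm events match chromosome-level queries and same-arm queries.
event_matches <- function(events, chromosome, arm = NULL) {
  hit <- events$chromosome == normalize_chrom(chromosome)
  if (!is.null(arm)) hit <- hit & (is.na(events$arm) | events$arm == arm)
  hit
}

#' Count samples in a group carrying an event on a chromosome or arm
#'
#' A sample counts once toward (group, chromosome/arm, event) if it has at
#' least one matching event; the denominator is the group size.
#'
#' @param events event table (from [segments_to_events()] or
#'   [parse_event_tokens()]).
#' @param samples sample sheet.
#' @param group logical vector over `samples`, or predicate function.
#' @param chromosome chromosome token.
#' @param arm optional arm (`"p"`/`"q"`); NULL = chromosome level.
#' @param event `"gain"` or `"loss"`.
#' @return list with `count`, `denominator`, `samples` (the carriers).
#' @export
count_recurrence <- function(events, samples, group, chromosome, arm = NULL,
                             event = c("gain", "loss")) {
  event <- match.arg(event)
  if (is.function(group)) group <- group(samples)
  unknown <- setdiff(unique(events$sample_id), samples$sample_id)
  if (length(unknown)) stop("unknown sample(s) in events: ",
                            paste(unknown, collapse = ", "))
  members <- samples$sample_id[group]
  hit <- event_matches(events, chromosome, arm) & events$event == event &
    events$sample_id %in% members
  carriers <- unique(events$sample_id[hit])
  list(count = length(carriers), denominator = length(members),
       samples = carriers)
}

#' Recurrence summaries across groups and chromosomes
#'
#' Tabulates, for each named group predicate and each chromosome (or arm)
#' present in the events, how many group members carry a gain and how many
#' a loss.
#'
#' @param events event table.
#' @param samples sample sheet.
#' @param groups named list of predicates (`function(samples) -> logical`)
#'   or logical vectors.
#' @param level `"chromosome"` or `"arm"`.
#' @return data.frame: group, chromosome, arm (NA at chromosome level),
#'   event, count, denominator.
#' @export
recurrence_by_group <- function(events, samples, groups,
                                level = c("chromosome", "arm")) {
  level <- match.arg(level)
  units <- unique(if (level == "chromosome") {
    data.frame(chromosome = events$chromosome, arm = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chromosome = events$chromosome,
               arm = ifelse(is.na(events$arm), "p", events$arm),
               stringsAsFactors = FALSE)
  })
  if (level == "arm") {
    # whole-chromosome events count toward both arms
    whole <- events[is.na(events$arm), , drop = FALSE]
    if (nrow(whole)) {
      units <- unique(rbind(units,
        data.frame(chromosome = whole$chromosome, arm = "q",
                   stringsAsFactors = FALSE)))
    }
  }
  rows <- list()
  for (gname in names(groups)) {
    for (i in seq_len(nrow(units))) {
      for (ev in c("gain", "loss")) {
        arm <- if (level == "arm") units$arm[i] else NULL
        r <- count_recurrence(events, samples, groups[[gname]],
                              units$chromosome[i], arm, ev)
        if (r$count == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          group = gname, chromosome = units$chromosome[i],
          arm = if (is.null(arm)) NA_character_ else arm,
          event = ev, count = r$count, denominator = r$denominator,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(group = character(), chromosome = character(),
                      arm = character(), event = character(),
                      count = integer(), denominator = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
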