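# Synthetic cohort generator: proteins with planted
# ordered/disordered/TM/DBR architecture, noisy score tracks, and
# on-disk cohorts in exactly the formats the readers consume. Ground
# truth is always returned so recovery can be checked end to end. A toy
# propensity predictor is included as an explicit stand-in for external
# disorder predictors (it is NOT a reimplementation of one).

# Residue pools biased by structural label, so that sequence composition
# correlates with planted disorder and the toy propensity predictor
# tracks ground truth.
VT_DISORDER_PROMOTING <- c("P", "E", "S", "Q", "K", "R", "G", "A")
VT_ORDER_PROMOTING    <- c("W", "F", "Y", "I", "L", "V", "C", "M", "N", "T")
VT_TM_RESIDUES        <- c("L", "I", "V", "F", "A", "M")

#' Expand a segment architecture into per-residue ground truth
#'
#' Deterministically expands an ordered list of
#' (length, label) segments — labels `ordered`, `disordered`, `tm` —
#' into a per-residue label vector, together with the TM segment table
#' and the planted DBR segments. DBRs must lie inside disordered
#' stretches.
#'
#' @param arch Data frame with columns `length` and `label`.
#' @param dbr_segments Segment table of planted binding regions.
#' @return List with `labels` (character vector, one per residue),
#'   `tm_segments` and `dbr_segments`.
#' @export
#' @examples
#' plant_architecture(data.frame(length = c(100, 100),
#'                               label = c("disordered", "ordered")))
plant_architecture <- function(arch, dbr_segments = segments()) {
  stopifnot(is.data.frame(arch), all(c("length", "label") %in% names(arch)))
  if (!nrow(arch) || sum(arch$length) < 1L) {
    stop("architecture must contain at least one residue", call. = FALSE)
  }
  bad <- setdiff(arch$label, c("ordered", "disordered", "tm"))
  if (length(bad)) {
    stop(sprintf("unknown architecture label '%s'", bad[1]), call. = FALSE)
  }
  labels <- rep(arch$label, arch$length)
  ends <- cumsum(arch$length)
  starts <- ends - arch$length + 1L
  tm_idx <- which(arch$label == "tm")
  tm <- segments(starts[tm_idx], ends[tm_idx])
  for (i in seq_len(nrow(dbr_segments))) {
    idx <- dbr_segments$start[i]:dbr_segments$end[i]
    if (dbr_segments$end[i] > length(labels) ||
        any(labels[idx] != "disordered")) {
      stop(sprintf("DBR %d-%d does not lie inside a disordered stretch",
                   dbr_segments$start[i], dbr_segments$end[i]),
           call. = FALSE)
    }
  }
  list(labels = labels, tm_segments = tm, dbr_segments = dbr_segments)
}

#' Synthesize noisy score tracks from ground-truth labels
#'
#' Disorder scores are drawn around 0.8 for disordered residues and 0.2
#' for ordered (and TM) residues, with Gaussian noise of standard
#' deviation `noise_sd` clipped to \[0, 1\]; the binding track is built
#' the same way over the DBR labels. With `noise_sd = 0` scores are
#' exactly 0.8/0.2 and binarization recovers the labels perfectly.
#'
#' @param labels Per-residue label vector from [plant_architecture()].
#' @param dbr_segments Planted DBR segment table.
#' @param noise_sd Noise standard deviation (`>= 0`).
#' @param seed Optional integer seed for reproducible tracks.
#' @param center_high,center_low Score centers for positive/negative
#'   residues.
#' @return List with `disorder` and `binding` [score_track()]s.
#' @export
synth_tracks <- function(labels, dbr_segments = segments(), noise_sd = 0.05,
                         seed = NULL, center_high = 0.8, center_low = 0.2) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  dis_center <- ifelse(labels == "disordered", center_high, center_low)
  dbr_flag <- segment_mask(dbr_segments, n)
  bind_center <- ifelse(dbr_flag, center_high, center_low)
  clip01 <- function(x) pmin(1, pmax(0, x))
  dis <- clip01(dis_center + rnorm(n, 0, noise_sd))
  bind <- clip01(bind_center + rnorm(n, 0, noise_sd))
  list(disorder = score_track(dis, "disorder"),
       binding = score_track(bind, "binding"))
}

# Sample a sequence whose composition follows the per-residue labels.
synth_sequence <- function(labels) {
  pools <- list(ordered = VT_ORDER_PROMOTING,
                disordered = VT_DISORDER_PROMOTING,
                tm = VT_TM_RESIDUES)
  paste(vapply(labels, function(l) sample(pools[[l]], 1L), ""),
        collapse = "")
}

# Architecture for one protein with planted disorder fraction `p`:
# a single contiguous disordered block (yielding realistic LDRs) at a
# random offset, optionally a TM helix inside the ordered part, and a
# DBR inside the disordered block.
synth_protein_arch <- function(len, p, tm = FALSE, dbr_prob = 0.5) {
  d <- round(p * len)
  d <- max(0L, min(len, d))
  o <- len - d
  lead <- if (o > 0L) sample.int(o + 1L, 1L) - 1L else 0L
  parts <- data.frame(length = c(lead, d, o - lead),
                      label = c("ordered", "disordered", "ordered"))
  parts <- parts[parts$length > 0L, , drop = FALSE]
  if (tm && o >= 25L) {
    # carve a 21-residue TM helix out of the longest ordered part
    oi <- which(parts$label == "ordered")
    oi <- oi[which.max(parts$length[oi])]
    olen <- parts$length[oi]
    if (olen >= 23L) {
      before <- sample.int(olen - 21L - 1L, 1L)
      repl <- data.frame(length = c(before, 21L, olen - 21L - before),
                         label = c("ordered", "tm", "ordered"))
      repl <- repl[repl$length > 0L, , drop = FALSE]
      parts <- rbind(parts[seq_len(oi - 1L), , drop = FALSE], repl,
                     parts[-seq_len(oi), , drop = FALSE])
    }
  }
  dbr <- segments()
  if (d >= 12L && runif(1) < dbr_prob) {
    ends <- cumsum(parts$length)
    di <- which(parts$label == "disordered")[1]
    dstart <- ends[di] - parts$length[di] + 1L
    dbr_len <- sample(6L:min(30L, d), 1L)
    off <- sample.int(d - dbr_len + 1L, 1L) - 1L
    dbr <- segments(dstart + off, dstart + off + dbr_len - 1L)
  }
  list(arch = parts, dbr = dbr)
}

#' Generate a synthetic cohort on disk
#'
#' Draws, per group, `n` proteins whose planted disorder fractions come
#' from a clipped normal around `target_mean_dc`, builds their segment
#' architectures, sequences and noisy score tracks, and writes exactly
#' the file formats the readers consume: `proteins.fasta`,
#' `annotations.tsv`, and per-protein `tracks/<accession>.iupred` /
#' `.anchor` files.
#'
#' @param groups Data frame with columns `label` (used as both functional
#'   route/group tag and accession prefix), `n`, `target_mean_dc`,
#'   `dc_sd`, `len_min`, `len_max`.
#' @param dir Output directory (created if needed).
#' @param noise_sd Track noise standard deviation.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param tm_prob Probability a protein carries one 21-residue TM helix.
#' @param species Species tag written to the annotation table.
#' @return Invisibly, a list with the file `paths` and a `truth` data
#'   frame (accession, group, planted disorder fraction, realized
#'   fraction).
#' @export
synth_cohort <- function(groups, dir, noise_sd = 0.05, seed = 1L,
                         tm_prob = 0, species = "human") {
  stopifnot(is.data.frame(groups),
            all(c("label", "n", "target_mean_dc", "dc_sd",
                  "len_min", "len_max") %in% names(groups)))
  if (any(groups$n < 1L)) stop("each group needs n >= 1", call. = FALSE)
  if (any(groups$target_mean_dc < 0 | groups$target_mean_dc > 1)) {
    stop("target_mean_dc must lie in [0,1]", call. = FALSE)
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }
  track_dir <- file.path(dir, "tracks")
  dir.create(track_dir, showWarnings = FALSE)
  set.seed(seed)

  seqs <- character()
  records <- list()
  truth <- list()
  for (gi in seq_len(nrow(groups))) {
    grp <- groups[gi, ]
    route <- if (grp$label %in% VT_ROUTES) grp$label else character()
    fgroup <- if (grp$label %in% VT_GROUPS) grp$label else "NONE"
    for (i in seq_len(grp$n)) {
      acc <- sprintf("%s%04d", gsub("[^A-Za-z0-9]", "", grp$label), i)
      len <- sample(grp$len_min:grp$len_max, 1L)
      p <- pmin(0.98, pmax(0.02, rnorm(1, grp$target_mean_dc, grp$dc_sd)))
      pa <- synth_protein_arch(len, p, tm = runif(1) < tm_prob)
      planted <- plant_architecture(pa$arch, pa$dbr)
      seq <- synth_sequence(planted$labels)
      tracks <- synth_tracks(planted$labels, planted$dbr_segments, noise_sd)
      rec <- protein_record(acc, seq, name = acc, species = species,
                            functional_group = fgroup, routes = route,
                            tm_segments = planted$tm_segments)
      write_score_track(tracks$disorder,
                        file.path(track_dir, paste0(acc, ".iupred")),
                        sequence = seq)
      write_score_track(tracks$binding,
                        file.path(track_dir, paste0(acc, ".anchor")),
                        sequence = seq)
      seqs[acc] <- seq
      records[[length(records) + 1L]] <- rec
      tm_mask <- segment_mask(planted$tm_segments, len)
      truth[[length(truth) + 1L]] <- data.frame(
        accession = acc, group = grp$label, length = len,
        planted_dc = p,
        realized_dc = sum(planted$labels == "disordered" & !tm_mask) /
          max(1L, sum(!tm_mask)))
    }
  }
  fasta <- file.path(dir, "proteins.fasta")
  ann <- file.path(dir, "annotations.tsv")
  write_fasta(seqs, fasta)
  write_annotation_table(records, ann)
  invisible(list(paths = list(fasta = fasta, annotations = ann,
                              track_dir = track_dir),
                 truth = do.call(rbind, truth)))
}

#' Synthetic tissue-specific-exon table for a cohort
#'
#' Draws, for a sample of cohort proteins, one TSE record each with a
#' random CDS exon structure consistent with the protein length and a
#' uniform switch score, in the shape [read_tse_table()] reads.
#'
#' @param truth Truth table from [synth_cohort()].
#' @param records Protein records of the cohort.
#' @param n Number of TSE records to draw.
#' @param seed Integer seed.
#' @return Data frame in the TSE-table shape (plus `accession`).
#' @export
synth_tse_table <- function(truth, records, n = 10L, seed = 1L) {
  set.seed(seed)
  acc <- vapply(records, `[[`, "", "accession")
  lens <- setNames(vapply(records, function(r) nchar(r$sequence), 1L), acc)
  pick <- sample(acc, min(n, length(acc)))
  rows <- lapply(pick, function(a) {
    L <- lens[[a]]
    n_exons <- sample(2:5, 1L)
    cuts <- sort(sample(seq_len(3L * L - 1L), n_exons - 1L))
    exon_lens <- diff(c(0L, cuts, 3L * L))
    rec <- records[[which(acc == a)]]
    data.frame(gene = a, transcript_id = paste0("T_", a),
               accession = a,
               switch_score = round(runif(1), 2),
               route = paste(rec$routes, collapse = ";"),
               functional_group = rec$functional_group,
               coding = TRUE,
               cds_exon_lengths = paste(exon_lens, collapse = ";"),
               tse_exon_index = sample(seq_len(n_exons), 1L),
               protein_span = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$protein_start <- NA_integer_
  out$protein_end <- NA_integer_
  out
}

#' Toy sliding-window disorder propensity predictor
#'
#' A deliberately simple stand-in for external per-residue disorder
#' predictors, useful for generating plausibly shaped tracks from real
#' sequences in tests and examples: the sliding-window mean of a
#' per-residue disorder propensity scale, min-max squashed to \[0, 1\]
#' using the scale's own range. Edge residues use truncated windows.
#' This is not a reimplementation of any energy-based predictor.
#'
#' @param sequence Amino-acid string.
#' @param scale Named numeric propensity per residue; the default is a
#'   published composition-based disorder propensity scale
#'   (disorder-promoting residues like P/E/S/K score high,
#'   order-promoting ones like W/F/I/V score low).
#' @param window Odd window width (`>= 1`).
#' @return A disorder [score_track()].
#' @export
propensity_track <- function(sequence, scale = vt_propensity_scale(),
                             window = 21L) {
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  letters <- strsplit(toupper(sequence), "")[[1]]
  missing <- setdiff(unique(letters), names(scale))
  if (length(missing)) {
    warning(sprintf("residue(s) %s absent from the propensity scale; using the scale median",
                    paste(missing, collapse = ",")))
    scale[missing] <- median(scale)
  }
  vals <- unname(scale[letters])
  n <- length(vals)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, vals))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  means <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  rng <- range(scale)
  squashed <- (means - rng[1]) / (rng[2] - rng[1])
  score_track(pmin(1, pmax(0, squashed)), "disorder")
}

#' Default disorder propensity scale
#'
#' The TOP-IDP-style composition scale ranking residues by their
#' disorder-promoting tendency, shifted to no particular units; only the
#' ordering and spacing matter to [propensity_track()].
#'
#' @return Named numeric vector over the 20 amino acids plus X/B/Z/U.
#' @export
vt_propensity_scale <- function() {
  s <- c(W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
         L = -0.326, V = -0.121, N = 0.007, C = 0.020, T = 0.059,
         A = 0.060, G = 0.166, R = 0.180, D = 0.192, H = 0.303,
         Q = 0.318, S = 0.341, K = 0.586, E = 0.736, P = 0.987)
  c(s, X = unname(median(s)), B = unname((s[["N"]] + s[["D"]]) / 2),
    Z = unname((s[["Q"]] + s[["E"]]) / 2), U = unname(s[["C"]]))
}
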