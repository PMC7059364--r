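make_elements <- function(start, end, strand = "+", kind = "exon",
                          chrom = "c", phase = NA_integer_) {
  n <- max(length(start), length(end), length(strand))
  data.frame(element_id = sprintf("el_%d", seq_len(n)), kind = kind,
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), phase = as.integer(phase),
             parent_id = NA_character_, stringsAsFactors = FALSE)
}

make_signals <- function(start, end, strand = "+", chrom = "c",
                         peak_height = 50L) {
  n <- max(length(start), length(end), length(strand))
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n),
             peak_height = rep_len(as.integer(peak_height), n),
             n_protomotifs = 10L, stringsAsFactors = FALSE)
}

test_that("CDS genomic frame follows coordinates, strand and phase", {
  cl <- c(c = 3000L)
  expect_equal(cds_genomic_frame(make_elements(0, 9, "+", "CDS", phase = 0), cl), 1L)
  expect_equal(cds_genomic_frame(make_elements(1, 10, "+", "CDS", phase = 2), cl), 1L)
  expect_equal(cds_genomic_frame(make_elements(5, 14, "+", "CDS", phase = 0), cl), 3L)
  # minus strand: first in-frame codon's rightmost base is end - phase
  expect_equal(cds_genomic_frame(make_elements(0, 3000, "-", "CDS", phase = 0), cl), -1L)
  # end 2999, phase 1: first in-frame codon's rightmost base r = 2998,
  # so (L - r) mod 3 = 2 -> frame -3
  expect_equal(cds_genomic_frame(make_elements(0, 2999, "-", "CDS", phase = 1), cl), -3L)
  expect_error(cds_genomic_frame(make_elements(0, 9, "+", "exon"), cl), "CDS")
})

test_that("every planted (strand, frame) combination is recovered and translates", {
  fx <- generate_genome(fixture_params(genome_length = 30000L,
                                       n_coding_regions = 6L,
                                       frames = c(1L, 2L, 3L, -1L, -2L, -3L),
                                       seed = 3L))
  cds <- fx$elements[fx$elements$kind == "CDS", ]
  derived <- cds_genomic_frame(cds, fx$chrom_lengths)
  expect_setequal(derived, c(-3:-1, 1:3))
  expect_equal(derived, fx$regions$frame)
  tr <- six_frame_translate(fx$genome[[1]])
  for (i in seq_len(6)) {
    cmap <- tr[[sprintf("%+d", derived[i])]]$codon_map
    idx <- which(cmap[, "start"] >= cds$start[i] & cmap[, "end"] <= cds$end[i])
    pep <- paste(strsplit(tr[[sprintf("%+d", derived[i])]]$peptide,
                          "")[[1]][idx], collapse = "")
    expect_identical(pep, fx$regions$peptide[i])
    # and in no other frame
    for (f in setdiff(names(tr), sprintf("%+d", derived[i]))) {
      expect_false(grepl(sub("\\*$", "", fx$regions$peptide[i]),
                         tr[[f]]$peptide, fixed = TRUE))
    }
  }
})

test_that("the 20% overlap rule is a closed bound on either fraction", {
  el <- make_elements(100, 200)
  # exactly 20% of the exon covered -> match
  expect_true(match_signals_to_elements(make_signals(180, 400), el)[1, 1])
  # just under on both fractions -> no match
  expect_false(match_signals_to_elements(make_signals(195, 400), el)[1, 1])
  # 20% of the signal underlies the exon -> match even at tiny exon coverage
  expect_true(match_signals_to_elements(make_signals(190, 240), el)[1, 1])
  # adjacency is not overlap
  expect_false(match_signals_to_elements(make_signals(200, 400), el)[1, 1])
})

test_that("strand policy gates matching; 'ignore' lifts it", {
  el <- make_elements(100, 200, "+")
  sig <- make_signals(100, 200, "-")
  expect_false(match_signals_to_elements(sig, el)[1, 1])
  expect_true(match_signals_to_elements(sig, el,
                                        eval_params(strand_mode = "ignore"))[1, 1])
  # unstranded elements match either strand
  expect_true(match_signals_to_elements(sig, make_elements(100, 200, "*"))[1, 1])
})

test_that("matching equals a brute-force all-pairs check on random input", {
  set.seed(33)
  n <- 40L
  el <- make_elements(sample.int(5000L, n), 0, strand = sample(c("+", "-"), n, TRUE))
  el$end <- el$start + sample.int(400L, n)
  sig <- make_signals(sample.int(5000L, n), 0, strand = sample(c("+", "-"), n, TRUE))
  sig$end <- sig$start + sample.int(400L, n)
  prm <- eval_params()
  m <- match_signals_to_elements(sig, el, prm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov <- brute_overlap_len(sig[i, ], el[j, ])
      want <- sig$strand[i] == el$strand[j] &&
        (ov / (el$end[j] - el$start[j]) >= 0.2 ||
           ov / (sig$end[i] - sig$start[i]) >= 0.2)
      if (m[i, j] != want) fail(sprintf("pair (%d, %d) mismatch", i, j))
    }
  }
  expect_true(all(m[sig$strand[row(m)] != el$strand[col(m)]] == FALSE))
})

test_that("evaluation implements the percent formulas and partitions", {
  el <- make_elements(c(100, 1000, 2000, 3000, 4000),
                      c(300, 1200, 2200, 3200, 4200))
  # 9 TP (matching the first four elements) + 1 FP
  sig <- make_signals(c(100, 150, 1000, 1050, 2000, 2050, 3000, 3050, 3100, 9000),
                      c(300, 350, 1200, 1250, 2200, 2250, 3200, 3250, 3300, 9100))
  ev <- evaluate(sig, el)
  expect_equal(unname(ev$counts), c(9L, 1L, 1L, 4L))
  expect_equal(ev$precision, 90)
  expect_equal(ev$recall, 100 * 4 / 5)
  expect_equal(sum(ev$counts[c("TP", "FP")]), nrow(sig))
  expect_equal(sum(ev$counts[c("found", "FN")]), nrow(el))
  # degenerate: no signals -> precision undefined, recall 0
  expect_warning(ev0 <- evaluate(sig[0, ], el), "precision undefined")
  expect_true(is.nan(ev0$precision))
  expect_equal(ev0$recall, 0)
})

test_that("a planted fixture with no background is scored perfectly", {
  prm <- fixture_params(genome_length = 50000L, n_coding_regions = 4L,
                        background_hits_per_kb = 0, decoy_cluster_rate = 0,
                        frame_shift_prob = 0, opposite_strand_prob = 0,
                        seed = 8L)
  fx <- generate_genome(prm)
  hits <- simulate_hits(fx)
  scan <- protomotif_scan(hits, fx$chrom_lengths,
                          profiler_params(peak_height_min = 20L))
  ev <- evaluate(scan, fx$elements[fx$elements$kind == "exon", ])
  expect_equal(ev$precision, 100)
  expect_equal(ev$recall, 100)
})

test_that("threshold sweep rows agree with single evaluations and a plateau forms", {
  fx <- generate_genome(fixture_params(genome_length = 40000L,
                                       n_coding_regions = 3L,
                                       background_hits_per_kb = 1,
                                       seed = 12L))
  hits <- simulate_hits(fx)
  pm <- filter_and_map(hits, profiler_params(), fx$chrom_lengths)
  prof <- build_profiles(pm, fx$chrom_lengths)
  el <- fx$elements[fx$elements$kind == "exon", ]
  maxd <- max(vapply(unlist(prof, recursive = FALSE),
                     function(p) max(p$depth), integer(1)))
  bg_max <- {
    # background depth ceiling: max depth outside any flanked planted region
    d <- prof[[1]][["+"]]$depth + prof[[1]][["-"]]$depth
    mask <- rep(TRUE, length(d))
    for (i in seq_len(nrow(fx$regions))) {
      lo <- max(1L, fx$regions$start[i] - 200L)
      hi <- min(length(d), fx$regions$end[i] + 200L)
      mask[lo:hi] <- FALSE
    }
    max(c(0L, d[mask]))
  }
  sw <- sweep_thresholds(prof, el, H_values = seq(1L, maxd, by = 4L))
  expect_equal(sw$TP + sw$FP, sw$n_signals)
  # recall and covered counts non-increasing in H
  expect_true(all(diff(sw$recall) <= 1e-9))
  expect_true(all(diff(sw$TP) <= 0L))
  expect_true(all(diff(sw$FP) <= 0L))
  # every H above the background ceiling and below the weakest planted peak
  # gives the same perfect row
  plateau <- sw[sw$H > bg_max &
                  sw$H <= min(vapply(seq_len(nrow(fx$regions)), function(i) {
                    s <- if (fx$regions$strand[i] == "+") "+" else "-"
                    max_depth_over(prof[[1]][[s]], fx$regions$start[i],
                                   fx$regions$end[i])
                  }, integer(1))), ]
  expect_gt(nrow(plateau), 1L)
  expect_true(all(plateau$precision == 100))
  expect_equal(length(unique(plateau$recall)), 1L)
  # H above the global maximum: no signals
  sw_hi <- suppressWarnings(sweep_thresholds(prof, el, maxd + 1L))
  expect_equal(sw_hi$n_signals, 0L)
  expect_equal(sw_hi$recall, 0)
  expect_error(sweep_thresholds(prof, el, integer()), "non-empty")
})

test_that("element binning applies the count rule before the height bins", {
  # element with 3 supporting protomotifs but a tall foreign peak
  pm <- data.frame(chrom = "c", start = c(10L, 12L, 14L), end = c(40L, 42L, 44L),
                   strand = "+", frame = 1L, bit_score = 35, e_value = 1e-3,
                   subject_id = "s", stringsAsFactors = FALSE)
  prof <- build_profiles(pm, c(c = 1000L))
  prof$c[["+"]]$depth[20] <- 90L  # imposed tall spike
  el <- make_elements(5, 50)
  b <- bin_elements(el, prof, pm)
  expect_equal(b$n_protomotifs, 3L)
  expect_equal(b$bin, "FN_lt5")
  # closed upper edge of the middle bin
  pm40 <- data.frame(chrom = "c", start = rep(100L, 40), end = rep(200L, 40),
                     strand = "+", frame = 1L, bit_score = 35, e_value = 1e-3,
                     subject_id = "s", stringsAsFactors = FALSE)
  pm40$end[1:5] <- 150L
  prof40 <- build_profiles(pm40, c(c = 1000L))
  el40 <- make_elements(120, 190)
  b40 <- bin_elements(el40, prof40, pm40)
  expect_equal(b40$peak_height, 40L)
  expect_equal(b40$bin, "gt35")
  prof35 <- prof40
  prof35$c[["+"]]$depth <- pmin(prof35$c[["+"]]$depth, 35L)
  expect_equal(bin_elements(el40, prof35, pm40)$bin, "26_35")
  prof25 <- prof40
  prof25$c[["+"]]$depth <- pmin(prof25$c[["+"]]$depth, 25L)
  expect_equal(bin_elements(el40, prof25, pm40)$bin, "lt26")
})

test_that("element bins equal a brute-force recount on a random fixture", {
  fx <- generate_genome(fixture_params(genome_length = 40000L,
                                       n_coding_regions = 4L,
                                       background_hits_per_kb = 3,
                                       seed = 44L))
  hits <- simulate_hits(fx)
  pm <- filter_and_map(hits, profiler_params(), fx$chrom_lengths)
  prof <- build_profiles(pm, fx$chrom_lengths)
  el <- fx$elements[fx$elements$kind == "exon", ]
  b <- bin_elements(el, prof, pm)
  L <- fx$chrom_lengths[[1]]
  for (i in seq_len(nrow(el))) {
    fs <- max(0L, el$start[i] - 100L); fe <- min(L, el$end[i] + 100L)
    sub <- pm[pm$strand == el$strand[i] & pm$start < fe & pm$end > fs, ]
    expect_equal(b$n_protomotifs[i], nrow(sub))
    depth <- brute_pileup(sub, L)
    expect_equal(b$peak_height[i], max(c(0L, depth[(fs + 1L):fe])))
    want <- if (nrow(sub) < 5) "FN_lt5" else if (b$peak_height[i] < 26)
      "lt26" else if (b$peak_height[i] <= 35) "26_35" else "gt35"
    expect_equal(b$bin[i], want)
  }
})

test_that("frame distribution counts per (CDS, protomotif, score-bin) incidence", {
  cl <- c(c = 3000L)
  cds <- make_elements(9, 30, "+", "CDS", phase = 0)  # frame +1
  pm <- data.frame(chrom = "c", start = 12L, end = 21L, strand = "+",
                   frame = 1L, bit_score = 45, e_value = 1e-3,
                   subject_id = "s", stringsAsFactors = FALSE)
  arr <- frame_distribution(pm, cds, c(30, 60), cl)
  expect_equal(sum(arr), 1L)
  expect_equal(arr["+1", "+1", 1], 1L)
  # opposite-strand protomotif lands off-diagonal, never on it
  pm$frame <- -2L; pm$strand <- "-"
  arr2 <- frame_distribution(pm, cds, c(30, 60), cl)
  expect_equal(arr2["+1", "-2", 1], 1L)
  expect_equal(sum(diag(arr2[, , 1])), 0L)
  # truth-conditioned fixture: hits only in the true frame -> all mass diagonal
  fx <- generate_genome(fixture_params(genome_length = 30000L,
                                       n_coding_regions = 4L,
                                       background_hits_per_kb = 0,
                                       frame_shift_prob = 0,
                                       opposite_strand_prob = 0, seed = 21L))
  hits <- simulate_hits(fx)
  pm_fx <- filter_and_map(hits, profiler_params(), fx$chrom_lengths)
  cds_fx <- fx$elements[fx$elements$kind == "CDS", ]
  arr3 <- frame_distribution(pm_fx, cds_fx, c(30, 60, 100), fx$chrom_lengths)
  expect_gt(sum(arr3), 0L)
  offdiag <- sum(arr3) - sum(vapply(1:2, function(b) sum(diag(arr3[, , b])),
                                    numeric(1)))
  expect_equal(offdiag, 0)
  # total equals brute-force incidence count
  inc <- 0L
  for (j in seq_len(nrow(cds_fx))) {
    inc <- inc + sum(pm_fx$start < cds_fx$end[j] & pm_fx$end > cds_fx$start[j] &
                       pm_fx$bit_score >= 30 & pm_fx$bit_score <= 100)
  }
  expect_equal(sum(arr3), inc)
})
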