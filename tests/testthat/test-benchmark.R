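truth2 <- tibble::tibble(gene5 = c("A", "C"), gene3 = c("B", "D"),
                         breakpoint5 = c("chr1:100:+", "chr2:50:+"),
                         breakpoint3 = c("chr2:900:-", "chr3:70:+"))

test_that("gene-pair matching honours order, allow-reverse, and proxy equivalences", {
  expect_equal(gene_pair_match("A", "B", truth2, "strict"), 1L)
  expect_true(is.na(gene_pair_match("B", "A", truth2, "strict")))
  expect_equal(gene_pair_match("B", "A", truth2, "allow_reverse"), 1L)
  # paralog proxy on one side
  par <- tempfile(); writeLines("A\tA2", par)
  simmap <- read_similarity_map(NULL, par)
  expect_equal(gene_pair_match("A2", "B", truth2, "strict", similarity = simmap), 1L)
  # genomic-overlap proxy
  ovl <- tibble::tibble(gene1 = "B", gene2 = "Bov")
  expect_equal(gene_pair_match("A", "Bov", truth2, "strict", overlap_pairs = ovl), 1L)
  expect_true(is.na(gene_pair_match("A", "Z", truth2, "allow_reverse",
                                    similarity = simmap, overlap_pairs = ovl)))
})

test_that("breakpoint matching sorts pairs and applies the 5-base fuzzy window", {
  a <- c("chr1:100:+", "chr2:900:-")
  expect_true(breakpoint_match(a, a, "exact"))
  expect_true(breakpoint_match(rev(a), a, "exact"))       # order ignored
  shifted <- c("chr1:105:+", "chr2:895:-")
  expect_false(breakpoint_match(shifted, a, "exact"))
  expect_true(breakpoint_match(shifted, a, "fuzzy"))      # +5 / -5 inside
  expect_false(breakpoint_match(c("chr1:106:+", "chr2:900:-"), a, "fuzzy"))
  expect_false(breakpoint_match(c("chr9:100:+", "chr2:900:-"), a, "fuzzy"))
})

test_that("scoring counts TP per truth entry and restricts FPs to unique predictions", {
  preds <- tibble::tibble(gene5 = c("A", "X"), gene3 = c("B", "Y"),
                          num_reads = c(5L, 2L))
  s <- score_predictions(preds, truth2)
  expect_equal(s$summary$TP, 1L); expect_equal(s$summary$FN, 1L)
  expect_equal(s$summary$FP, 1L)
  expect_equal(s$fn$gene5, "C")
  # perfect predictions: FP = FN = 0, P = R = F1 = 1
  perf <- tibble::tibble(gene5 = truth2$gene5, gene3 = truth2$gene3,
                         num_reads = 3L)
  sp <- score_predictions(perf, truth2)
  expect_equal(sp$summary[c("precision", "recall", "f1")],
               tibble::tibble(precision = 1, recall = 1, f1 = 1))
  # two predictions hitting one truth entry still count one TP
  dup <- dplyr::bind_rows(preds[1, ], preds[1, ])
  expect_equal(score_predictions(dup, truth2)$summary$TP, 1L)
  # shared (cross-method) false calls are excluded under unique-FP scoring
  others <- tibble::tibble(method = "m2", gene5 = "X", gene3 = "Y")
  su <- score_predictions(preds, truth2, other_methods_preds = others)
  expect_equal(su$summary$FP, 0L)
  # read-support filtering is monotone in TP
  expect_lte(score_predictions(preds, truth2, min_reads = 6)$summary$TP,
             score_predictions(preds, truth2, min_reads = 1)$summary$TP)
})

test_that("the PR curve and its AUC follow the trapezoid convention", {
  # perfect predictor at every threshold -> AUC 1
  perf <- tibble::tibble(gene5 = truth2$gene5, gene3 = truth2$gene3,
                         num_reads = 10L)
  pr <- pr_curve_auc(perf, truth2, thresholds = 1:10)
  expect_equal(pr$auc, 1)
  # single point P=1, R=0.5 extended to recall 0 -> AUC 0.5
  half <- tibble::tibble(gene5 = "A", gene3 = "B", num_reads = 1L)
  pr2 <- pr_curve_auc(half, truth2, thresholds = 1L)
  expect_equal(pr2$points$precision, 1)
  expect_equal(pr2$points$recall, 0.5)
  expect_equal(pr2$auc, 0.5)
  # degenerate: no predictions -> AUC 0 with flagged points
  expect_message(
    pr0 <- pr_curve_auc(half[0, ], truth2, thresholds = 1L), "AUC = 0")
  expect_equal(pr0$auc, 0)
  expect_true(all(pr0$points$flagged))

  # random instances vs an independent shoelace-polygon oracle
  set.seed(77)
  for (trial in 1:20) {
    genes <- sprintf("g%02d", 1:12)
    tr <- tibble::tibble(gene5 = sample(genes, 4), gene3 = sample(genes, 4))
    pd <- tibble::tibble(gene5 = sample(genes, 8, TRUE),
                         gene3 = sample(genes, 8, TRUE),
                         num_reads = sample.int(6, 8, TRUE)) |>
      dplyr::filter(gene5 != gene3)
    pr <- pr_curve_auc(pd, tr, thresholds = 1:6)
    pts <- dplyr::filter(pr$points, !flagged)
    if (nrow(pts) == 0) { expect_equal(pr$auc, 0); next }
    best <- dplyr::arrange(
      dplyr::summarise(dplyr::group_by(pts, recall),
                       precision = max(precision), .groups = "drop"), recall)
    # polygon under the curve: (0,0) -> (0,pmax) -> points -> (rmax,0)
    xs <- c(0, 0, best$recall, max(best$recall))
    ys <- c(0, max(best$precision), best$precision, 0)
    shoelace <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    expect_lt(abs(pr$auc - shoelace), 1e-12)
  }
})

test_that("proxy truth sets equal exhaustive enumeration on a four-method table", {
  set.seed(13)
  genes <- sprintf("g%d", 1:8)
  methods <- paste0("M", 1:4)
  preds_all <- purrr::map_dfr(methods, function(m) {
    n <- 12
    tibble::tibble(method = m,
                   gene5 = sample(genes, n, TRUE), gene3 = sample(genes, n, TRUE),
                   num_reads = sample.int(8, n, TRUE)) |>
      dplyr::filter(gene5 != gene3)
  })
  for (mm in 2:4) for (mr in c(1L, 3L, 6L)) {
    got <- build_proxy_truth(preds_all, min_reads = mr, min_methods = mm)
    # oracle: count methods per unordered pair after read filtering
    f <- dplyr::filter(preds_all, num_reads >= mr)
    key <- paste(pmin(f$gene5, f$gene3), pmax(f$gene5, f$gene3))
    want <- sort(names(which(
      tapply(f$method, key, function(x) length(unique(x))) >= mm)))
    expect_equal(sort(paste(got$gene5, got$gene3)), want,
                 label = sprintf("mm=%d mr=%d", mm, mr))
  }
  # a pair called by a single method can never enter the truth set
  solo <- tibble::tibble(method = "M1", gene5 = "u1", gene3 = "u2",
                         num_reads = 99L)
  got <- build_proxy_truth(dplyr::bind_rows(preds_all, solo), 1L, 2L)
  expect_false(any(got$gene5 == "u1"))
  # grid sweep covers 3 x 10 cells
  grid <- proxy_truth_grid(preds_all)
  expect_equal(nrow(grid), 30L)
})

test_that("nuisance filtering removes mito/HLA/IG partners, neighbors, normals and promiscuous genes", {
  gms <- gene_model_set(tibble::tibble(
    gene_id = c("N1", "N2", "F1", "MTG"),
    transcript_id = paste0(c("N1", "N2", "F1", "MTG"), ".t"),
    chrom = c("chr1", "chr1", "chr2", "chrM"), strand = "+",
    start = c(0L, 80000L, 0L, 0L), end = c(1000L, 81000L, 1000L, 500L)))
  preds <- tibble::tibble(
    gene5 = c("MTG", "HLA-A", "IGH", "N1", "A", "F1"),
    gene3 = c("X1", "X2", "X3", "N2", "B", "X4"),
    num_reads = 3L)
  got <- nuisance_filter(
    preds, gms, hla_genes = "HLA-A", ig_genes = "IGH",
    normal_fusions = c("A--B"))
  # N1--N2 are 79 kb apart on chr1 -> removed as neighbors
  expect_equal(got$gene5, "F1")
  # 120 kb apart -> kept
  gms2 <- gene_model_set(tibble::tibble(
    gene_id = c("N1", "N2"), transcript_id = c("N1.t", "N2.t"),
    chrom = "chr1", strand = "+", start = c(0L, 121000L),
    end = c(1000L, 122000L)))
  far <- tibble::tibble(gene5 = "N1", gene3 = "N2", num_reads = 3L)
  expect_equal(nrow(nuisance_filter(far, gms2)), 1L)
  # exactly 100 kb gap is removed (ties at the threshold)
  gms3 <- gene_model_set(tibble::tibble(
    gene_id = c("N1", "N2"), transcript_id = c("N1.t", "N2.t"),
    chrom = "chr1", strand = "+", start = c(0L, 101000L),
    end = c(1000L, 102000L)))
  expect_equal(nrow(nuisance_filter(far, gms3)), 0L)

  # promiscuous gene: called by 2 methods across 3 samples
  cross <- tibble::tibble(
    method = c("m1", "m2", "m1"), sample = c("s1", "s2", "s3"),
    gene5 = "P", gene3 = c("q1", "q2", "q3"))
  pp <- tibble::tibble(gene5 = c("P", "ok1"), gene3 = c("z", "ok2"),
                       num_reads = 1L)
  got2 <- nuisance_filter(pp, gms = NULL, cross_sample = cross)
  expect_equal(got2$gene5, "ok1")
})

test_that("matching containments hold over random instances", {
  set.seed(99)
  genes <- sprintf("g%d", 1:6)
  n <- 400
  for (i in seq_len(n)) {
    p <- sample(genes, 2); t <- sample(genes, 2)
    tr <- tibble::tibble(gene5 = t[1], gene3 = t[2])
    strict <- !is.na(gene_pair_match(p[1], p[2], tr, "strict"))
    loose <- !is.na(gene_pair_match(p[1], p[2], tr, "allow_reverse"))
    if (strict) expect_true(loose)
  }
  # exact breakpoint matches are a subset of fuzzy matches
  for (i in seq_len(n)) {
    base <- c(sample.int(1000, 1), sample.int(1000, 1))
    off <- sample(-8:8, 2, TRUE)
    a <- sprintf("chr1:%d:+", base)
    b <- sprintf("chr1:%d:+", base + off)
    if (breakpoint_match(a, b, "exact")) {
      expect_true(breakpoint_match(a, b, "fuzzy"))
    }
  }
})

test_that("a fusion report converts to the prediction dialect", {
  rep <- tibble::tibble(
    FusionName = c("A--B", "A--B", "C--D"),
    LeftGene = c("A", "A", "C"), LeftBreakpoint = c("c:1:+", "c:5:+", "c:9:+"),
    RightGene = c("B", "B", "D"),
    RightBreakpoint = c("c:2:-", "c:6:-", "c:8:-"),
    NumLongReads = c(7L, 3L, 2L), LR_FFPM = 1, SpliceType = "ONLY_REF_SPLICE",
    Annotations = ".", LongReadIds = "r")
  p <- as_predictions(rep, method = "m", sample = "s")
  expect_equal(nrow(p), 2L)
  ab <- p[p$gene5 == "A", ]
  expect_equal(ab$num_reads, 10L)          # summed over isoforms
  expect_equal(ab$breakpoint5, "c:1:+")    # dominant isoform's breakpoint
  expect_equal(nrow(as_predictions(rep, per_fusion = FALSE)), 3L)
})
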