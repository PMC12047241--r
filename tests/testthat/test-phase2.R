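aln_row <- function(read_id, cs, ce, rs = 0L, re = NULL) {
  if (is.null(re)) re <- rs + (ce - cs)
  tibble::tibble(read_id = read_id, contig_start = as.integer(cs),
                 contig_end = as.integer(ce), read_start = as.integer(rs),
                 read_end = as.integer(re))
}

test_that("alignment-end snapping moves only ends within the tolerance and is idempotent", {
  boundaries <- c(100L, 500L)
  a <- dplyr::bind_rows(
    aln_row("r", 98, 502),    # both ends within 3 -> snap to 100/500
    aln_row("s", 96, 504),    # both 4 away -> unchanged
    aln_row("t", 100, 500))   # already on boundaries -> unchanged
  got <- snap_alignment_ends(a, boundaries, snap_dist = 3L)
  expect_equal(got$contig_start, c(100L, 96L, 100L))
  expect_equal(got$contig_end, c(500L, 504L, 500L))
  # boundary+3 snaps, boundary+4 does not
  b <- snap_alignment_ends(aln_row("u", 103, 497), boundaries, 3L)
  expect_equal(c(b$contig_start, b$contig_end), c(100L, 500L))
  # idempotence
  expect_equal(snap_alignment_ends(got, boundaries, 3L), got)
})

# A two-gene simulated fixture gives a realistic contig for read
# classification tests.
phase2_fixture <- function() {
  sim <- tiny_sim()
  plan <- sim$fusion_plan[1, ]
  contig <- build_fusion_contig(sim$gms, sim$genome, plan$gene5, plan$gene3)
  list(sim = sim, plan = plan, contig = contig)
}

test_that("fusion-read classification needs 25 exonic bases in each gene and dissimilar exons", {
  fx <- phase2_fixture()
  contig <- fx$contig
  # junction on the contig: end of donor exon block and start of acceptor
  donor_end <- max(dplyr::filter(contig$exon_blocks,
                                 gene_id == contig$gene5)$contig_end)
  acceptor_start <- min(dplyr::filter(contig$exon_blocks,
                                      gene_id == contig$gene3)$contig_start)
  span <- function(id, left, right) {
    dplyr::bind_rows(aln_row(id, donor_end - left, donor_end),
                     aln_row(id, acceptor_start, acceptor_start + right,
                             rs = left))
  }
  got <- classify_fusion_reads(
    dplyr::bind_rows(span("ok", 30, 30), span("thin5", 20, 300),
                     span("thin3", 40, 24)),
    contig)
  expect_equal(got$is_evidence[got$read_id == "ok"], TRUE)
  expect_equal(got$is_evidence[got$read_id == "thin5"], FALSE)
  expect_equal(got$is_evidence[got$read_id == "thin3"], FALSE)
  expect_equal(got$break5[got$read_id == "ok"], donor_end)
  expect_equal(got$break3[got$read_id == "ok"], acceptor_start)

  # flag the 3' gene's aligned exon as sequence-similar to the 5' gene:
  # the evidence no longer counts
  g3first <- dplyr::filter(contig$exon_blocks, gene_id == contig$gene3)[1, ]
  g5first <- dplyr::filter(contig$exon_blocks, gene_id == contig$gene5)[1, ]
  sim_tsv <- tempfile()
  writeLines(sprintf("%s\t%s\t%s:%d-%d\t%s:%d-%d",
                     contig$gene5, contig$gene3,
                     g5first$chrom, g5first$genome_start + 1L, g5first$genome_end,
                     g3first$chrom, g3first$genome_start + 1L, g3first$genome_end),
             sim_tsv)
  simmap <- read_similarity_map(sim_tsv, NULL)
  got2 <- classify_fusion_reads(span("ok", 40, 40), contig, simmap)
  expect_false(got2$is_evidence)
})

test_that("breakpoint tallies group reads by snapped breakpoints with per-isoform counts", {
  # explicit two-isoform plan on one gene pair: 7 and 3 reads
  sim2 <- cached_sim("two_iso", {
    s <- sim_spec(seed = 12, n_genes = 6, background_reads = 20, sub_rate = 0,
                  fusion_plan = tibble::tibble(
                    gene5 = c("G01", "G01"), gene3 = c("G04", "G04"),
                    donor_exon = c(1L, 2L), acceptor_exon = c(2L, 2L),
                    n_reads = c(7L, 3L)))
    s
  })
  rep <- call_fusions(sim2$segments, sim2$gms, sim2$genome,
                      total_reads = nrow(sim2$reads),
                      aligner = ideal_aligner(sim2$read_blocks))
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$NumLongReads, c(7L, 3L))  # sorted by support
  expect_equal(unique(rep$FusionName), "G01--G04")
  expect_setequal(rep$LeftBreakpoint, unique(sim2$truth$breakpoint5))
  # each isoform's FFPM reflects its own count
  expect_equal(rep$LR_FFPM, compute_ffpm(c(7, 3), nrow(sim2$reads)))
})

test_that("splice classification reads the contig dinucleotide context", {
  fx <- phase2_fixture()
  contig <- fx$contig
  sim <- fx$sim
  # the planned junction, located by mapping the truth breakpoints onto
  # the contig: donor exon end (exclusive) and acceptor exon start
  bp5 <- sim$truth$breakpoint5[1]; bp3 <- sim$truth$breakpoint3[1]
  p5 <- strsplit(bp5, ":")[[1]]; p3 <- strsplit(bp3, ":")[[1]]
  donor_end <- genome_to_contig(contig, p5[1], as.integer(p5[2]) - 1L,
                                gene_id = contig$gene5)$contig_pos + 1L
  acceptor_start <- genome_to_contig(contig, p3[1], as.integer(p3[2]) - 1L,
                                     gene_id = contig$gene3)$contig_pos
  # real exon junction: GT donor / AG acceptor by construction
  got <- classify_splice(contig, donor_end, acceptor_start)
  expect_equal(got$donor, "GT"); expect_equal(got$acceptor, "AG")
  expect_equal(got$splice_class, "consensus")
  # contig edge: flagged non-consensus
  edge <- classify_splice(contig, nchar(contig$seq), 1L)
  expect_true(edge$edge); expect_equal(edge$splice_class, "non_consensus")
  # the consensus set is configurable: GT--AG fails a GC--AG-only set,
  # and an exotic pair passes when declared consensus
  only_gc <- fusion_config(consensus_sites = list(c("GC", "AG")))
  expect_equal(classify_splice(contig, donor_end, acceptor_start, only_gc)$splice_class,
               "non_consensus")
  with_gt <- fusion_config(consensus_sites = list(c("GC", "AG"), c("GT", "AG")))
  expect_equal(classify_splice(contig, donor_end, acceptor_start, with_gt)$splice_class,
               "consensus")
})

test_that("final filters enforce FFPM, non-consensus support, and the 5% isoform rule", {
  mk <- function(b5, n, splice, total = 1e6) {
    tibble::tibble(break5 = b5, break3 = 1000L, n_reads = n,
                   read_ids = list(sprintf("r%d", seq_len(n))),
                   fusion_name = "A--B", gene5 = "A", gene3 = "B",
                   breakpoint5 = "c:1:+", breakpoint3 = "c:2:+",
                   donor = "GT", acceptor = "AG", splice_class = splice,
                   ffpm = compute_ffpm(n, total))
  }
  # non-consensus: 1 read dropped, 2 reads kept
  expect_equal(nrow(apply_final_filters(mk(1L, 1L, "non_consensus"))), 0L)
  expect_equal(nrow(apply_final_filters(mk(1L, 2L, "non_consensus"))), 1L)
  # consensus: a single read suffices when FFPM passes
  expect_equal(nrow(apply_final_filters(mk(1L, 1L, "consensus"))), 1L)
  # FFPM floor: 1 read in 20 M = 0.05 drops even at consensus sites
  expect_equal(nrow(apply_final_filters(mk(1L, 1L, "consensus", total = 2e7))), 0L)
  # isoform noise: dominant 100 reads, sibling 4 dropped / 5 kept
  two <- dplyr::bind_rows(mk(1L, 100L, "consensus"), mk(2L, 4L, "consensus"))
  expect_equal(apply_final_filters(two)$n_reads, 100L)
  two$n_reads[2] <- 5L
  two$ffpm[2] <- compute_ffpm(5, 1e6)
  expect_equal(sort(apply_final_filters(two)$n_reads), c(5L, 100L))
})

test_that("filters are monotone in their thresholds", {
  fx <- phase2_fixture()
  sim <- fx$sim
  base_cfg <- fusion_config()
  run <- function(cfg) {
    rep <- call_fusions(sim$segments, sim$gms, sim$genome,
                        total_reads = nrow(sim$reads),
                        aligner = ideal_aligner(sim$read_blocks), config = cfg)
    paste(rep$FusionName, rep$LeftBreakpoint, rep$RightBreakpoint)
  }
  base <- run(base_cfg)
  stricter <- list(
    fusion_config(min_ffpm = 1000),
    fusion_config(min_identity = 0.95),
    fusion_config(min_exon_bp = 60L),
    fusion_config(min_reads_consensus = 5L, min_reads_nonconsensus = 8L),
    fusion_config(isoform_frac = 0.5),
    fusion_config(boundary_near = 5L, boundary_far = 10L))
  for (cfg in stricter) {
    expect_true(all(run(cfg) %in% base))
  }
})

test_that("fusion reports round-trip through the TSV dialect", {
  fx <- phase2_fixture()
  sim <- fx$sim
  rep <- call_fusions(sim$segments, sim$gms, sim$genome,
                      total_reads = nrow(sim$reads),
                      aligner = ideal_aligner(sim$read_blocks))
  path <- tempfile(fileext = ".tsv")
  write_fusion_report(rep, path)
  expect_true(startsWith(readLines(path, n = 1), "#FusionName\t"))
  back <- read_fusion_report(path)
  expect_equal(as.data.frame(back), as.data.frame(rep))

  # empty result: header-only file
  empty <- rep[0, ]
  p2 <- tempfile(); write_fusion_report(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(nrow(read_fusion_report(p2)), 0L)
})

test_that("reads from unrelated genes yield no contig alignment", {
  fx <- phase2_fixture()
  other <- dplyr::filter(fx$sim$read_blocks,
                         !gene_id %in% c(fx$contig$gene5, fx$contig$gene3))
  aln <- realign_to_contig(unique(other$read_id), fx$contig,
                           ideal_aligner(fx$sim$read_blocks))
  expect_equal(nrow(aln), 0L)
})
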