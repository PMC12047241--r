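seg_row <- function(read_id, chrom, gstart, gend, strand = "+",
                    rstart = 0L, rend = NULL, identity = 1) {
  if (is.null(rend)) rend <- rstart + (gend - gstart)
  blen <- gend - gstart
  tibble::tibble(read_id = read_id, read_len = 2000L,
                 read_start = as.integer(rstart), read_end = as.integer(rend),
                 align_strand = strand, chrom = chrom,
                 genome_start = as.integer(gstart), genome_end = as.integer(gend),
                 matches = as.integer(round(identity * blen)),
                 block_len = as.integer(blen), identity = identity)
}

test_that("chimeric collection keeps only reads split across distinct loci", {
  segs <- dplyr::bind_rows(
    seg_row("single", "chr1", 100, 400),
    seg_row("split", "chr1", 100, 400), seg_row("split", "chr9", 900, 1200, rstart = 300),
    # same chromosome, 10 kb apart: one locus at the default 100 kb gap
    seg_row("near", "chr2", 1000, 1500), seg_row("near", "chr2", 11500, 12000, rstart = 500),
    # same chromosome but far beyond the gap
    seg_row("far", "chr3", 1000, 1500), seg_row("far", "chr3", 201501, 202000, rstart = 500),
    # same chromosome, opposite strands
    seg_row("inv", "chr4", 1000, 1500), seg_row("inv", "chr4", 2000, 2500, "-", rstart = 500)
  )
  got <- collect_chimeric_reads(segs)
  expect_setequal(unique(got$read_id), c("split", "far", "inv"))
  # segments sorted by read coordinate within read
  expect_true(all(unlist(tapply(got$read_start, got$read_id,
                                function(x) !is.unsorted(x)))))

  # simulated fusion + background reads: exactly the fusion reads survive
  sim <- tiny_sim()
  chim <- collect_chimeric_reads(sim$segments)
  expect_setequal(unique(chim$read_id),
                  sim$reads$read_id[sim$reads$type == "fusion"])
})

test_that("segment-to-gene assignment maximises exonic overlap", {
  gms <- hand_gms()  # G1: chr1 [100,200)+[300,420); G2: chr2 [50,150)+[250,330)
  segs <- dplyr::bind_rows(
    seg_row("a", "chr1", 120, 180),   # inside exon 1 of G1
    seg_row("b", "chr1", 210, 290),   # wholly intronic
    seg_row("c", "chr2", 100, 160)    # overlaps G2 exon by 50
  )
  got <- assign_segment_gene(segs, gms)
  expect_equal(got$gene_id, c("G1", NA, "G2"))
  expect_equal(got$exonic_overlap, c(60L, 0L, 50L))

  # two overlapping single-exon genes: larger exonic overlap wins
  gms2 <- gene_model_set(tibble::tibble(
    gene_id = c("GA", "GB"), transcript_id = c("GA.t", "GB.t"),
    chrom = "chr5", strand = "+", start = c(0L, 80L), end = c(100L, 200L)))
  seg <- seg_row("d", "chr5", 20, 120)  # 80 bp in GA, 40 bp in GB
  expect_equal(assign_segment_gene(seg, gms2)$gene_id, "GA")
})

test_that("candidate derivation enforces identity and infers 5'/3' order with antisense flip", {
  gms <- hand_gms()
  # read: G1 part then G2 part, both sense; junction at G1 exon1 end (200)
  # and G2 exon1 (transcript rank 1 = genomic [250,330)) end, i.e. 250 on '-'
  segs <- dplyr::bind_rows(
    seg_row("r1", "chr1", 100, 200, "+", rstart = 0),
    seg_row("r1", "chr2", 250, 330, "-", rstart = 100))
  got <- derive_candidates(assign_segment_gene(segs, gms), gms)
  expect_equal(got$gene5, "G1"); expect_equal(got$gene3, "G2")
  expect_equal(got$dist5, 0L); expect_equal(got$dist3, 0L)

  # identity below 0.70 on either segment kills the candidate
  segs_low <- dplyr::bind_rows(
    seg_row("r2", "chr1", 100, 200, "+", rstart = 0, identity = 0.69),
    seg_row("r2", "chr2", 250, 330, "-", rstart = 100, identity = 0.99))
  expect_equal(nrow(derive_candidates(assign_segment_gene(segs_low, gms), gms)), 0L)
  segs_ok <- dplyr::bind_rows(
    seg_row("r3", "chr1", 100, 200, "+", rstart = 0, identity = 0.70),
    seg_row("r3", "chr2", 250, 330, "-", rstart = 100, identity = 0.99))
  expect_equal(nrow(derive_candidates(assign_segment_gene(segs_ok, gms), gms)), 1L)

  # antisense flip: reverse-complement read shows (G2-part, G1-part) with
  # both segments antisense; candidate must still be (G1, G2)
  segs_flip <- dplyr::bind_rows(
    seg_row("r4", "chr2", 250, 330, "+", rstart = 0),    # antisense to '-' gene
    seg_row("r4", "chr1", 100, 200, "-", rstart = 100))  # antisense to '+' gene
  gotf <- derive_candidates(assign_segment_gene(segs_flip, gms), gms)
  expect_equal(gotf$gene5, "G1"); expect_equal(gotf$gene3, "G2")
  expect_equal(gotf$dist5, 0L); expect_equal(gotf$dist3, 0L)
})

test_that("phase-1 retention applies the 50 bp / 1 kb boundary rules", {
  base <- tibble::tibble(
    gene5 = "A", gene3 = "B", break5_chrom = "c", break5_pos = 0L,
    break3_chrom = "c", break3_pos = 0L, identity5 = 1, identity3 = 1)
  mk <- function(read_id, d5, d3) {
    dplyr::bind_cols(tibble::tibble(read_id = read_id, dist5 = d5, dist3 = d3), base)
  }
  # both within 50: retained on a single read
  expect_equal(nrow(phase1_retention(mk("r1", 10L, 30L))), 1L)
  # mixed 50/1 kb rule requires multiple reads
  expect_equal(nrow(phase1_retention(mk("r1", 40L, 800L))), 0L)
  two <- dplyr::bind_rows(mk("r1", 40L, 800L), mk("r2", 45L, 900L))
  expect_equal(nrow(phase1_retention(two)), 2L)
  # neither rule satisfied regardless of support
  many <- dplyr::bind_rows(lapply(1:5, function(i) mk(paste0("r", i), 60L, 60L)))
  expect_equal(nrow(phase1_retention(many)), 0L)

  # monotone in read support: adding a read never removes a retained pair
  with_extra <- dplyr::bind_rows(two, mk("r3", 999L, 999L))
  expect_true(all(paste(phase1_retention(two)$read_id) %in%
                    paste(phase1_retention(with_extra)$read_id)))
})

test_that("FFPM follows its definition and rejects an empty sample", {
  expect_identical(compute_ffpm(1, 1e7), 0.1)
  expect_identical(compute_ffpm(0, 5e6), 0)
  expect_equal(compute_ffpm(37, 4e6), 9.25)
  expect_error(compute_ffpm(1, 0), "positive")
  # ratio preservation under a fixed total
  counts <- c(2, 4, 8)
  expect_equal(compute_ffpm(counts, 1e6) / compute_ffpm(counts[1], 1e6),
               counts / counts[1])
})

test_that("candidate filtering drops listed, overlapping, paralogous and low-FFPM pairs", {
  rc <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7"),
    gene5 = c("A", "B", "C", "D", "E", "E", "E"),
    gene3 = c("X", "Y", "Z", "W", "V", "V", "V"),
    dist5 = 0L, dist3 = 0L)
  par_tsv <- tempfile(); writeLines("C\tZ", par_tsv)
  simmap <- read_similarity_map(NULL, par_tsv)
  got <- filter_candidates(
    rc, total_reads = 2e7,
    overlap_pairs = tibble::tibble(gene1 = "B", gene2 = "Y"),
    similarity = simmap, red_herrings = c("A--X"))
  # A--X red herring, B--Y overlapping, C--Z paralogs, D--W 1 read/20M
  # (FFPM 0.05) all drop; E--V has 3 reads (FFPM 0.15) and survives
  expect_equal(got$gene5, "E")
  expect_equal(got$n_reads, 3L)
  expect_equal(got$ffpm, 0.15)
})
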