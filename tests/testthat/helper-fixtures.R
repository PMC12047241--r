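# Shared fixtures, all generated in code.

# Two hand-built genes on separate chromosomes with known coordinates:
# G1 (+, chr1) exons [100,200) and [300,420); G2 (-, chr2) exons [50,150)
# and [250,330).
hand_gms <- function() {
  gene_model_set(tibble::tibble(
    gene_id = c("G1", "G1", "G2", "G2"),
    transcript_id = c("G1.t1", "G1.t1", "G2.t1", "G2.t1"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "+", "-", "-"),
    start = c(100L, 300L, 50L, 250L),
    end = c(200L, 420L, 150L, 330L)
  ))
}

# Random genome covering the hand-built models, with GT..AG introns so
# splice classification behaves as on real annotation.
hand_genome <- function(seed = 1) {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # chr1: pad 100 | exon1 100 | intron GT..AG 100 | exon2 120 | pad 80
  chr1 <- paste0(rnd(100), rnd(100), "GT", rnd(96), "AG", rnd(120), rnd(80))
  # chr2: minus-strand gene; intron [150,250) must read GT..AG on the
  # minus strand => genomic CT..AC
  chr2 <- paste0(rnd(50), rnd(100), "CT", rnd(96), "AC", rnd(80), rnd(70))
  Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
}

# Small simulated dataset cache (one build per R session).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, spec) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, lrfuse::simulate_fusion_dataset(spec), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

tiny_sim <- function() {
  cached_sim("tiny", lrfuse::sim_spec(seed = 42, n_genes = 6, n_fusions = 1,
                                      background_reads = 12))
}

mid_sim <- function() {
  cached_sim("mid", lrfuse::sim_spec(seed = 7, n_genes = 10, n_fusions = 2,
                                     background_reads = 40))
}
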