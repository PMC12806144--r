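## Sequence fixtures with planted motif occurrences.
##
## The background model is i.i.d. nucleotides at a configurable GC
## content, rejection-sampled until the assembled sequence carries exactly
## the planted hit counts at the configured thresholds. This guarantees
## that a scan of any fixture recovers the planted counts exactly, which
## is what makes the fixtures usable as scanner oracles.

sample_background <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = probs)
}

revcomp_chars <- function(chars) {
  rev(c(A = "T", C = "G", G = "C", T = "A")[chars])
}

## Place planted sites without overlap into a window of `len` bases.
## Returns a data.frame (motif_id, start0, strand, site chars) or NULL if
## a placement could not be found.
place_sites <- function(site_seqs, len) {
  occupied <- rep(FALSE, len)
  out <- vector("list", length(site_seqs))
  ord <- if (length(site_seqs)) sample.int(length(site_seqs)) else integer(0)
  for (i in ord) {
    chars <- site_seqs[[i]]$chars
    L <- length(chars)
    starts <- seq_len(len - L + 1L)
    free <- !occupied
    ok <- vapply(starts, function(p) all(free[p:(p + L - 1L)]), logical(1))
    cand <- starts[ok]
    if (!length(cand)) return(NULL)
    p <- cand[sample.int(length(cand), 1L)]
    occupied[p:(p + L - 1L)] <- TRUE
    out[[i]] <- data.frame(motif_id = site_seqs[[i]]$motif_id,
                           start0 = p - 1L,
                           strand = site_seqs[[i]]$strand,
                           stringsAsFactors = FALSE)
    out[[i]]$chars <- list(chars)
  }
  do.call(rbind, out)
}

## Assemble a window: background everywhere, planted site characters
## overwriting their slots.
assemble_window <- function(sites, len, gc) {
  chars <- sample_background(len, gc)
  if (!is.null(sites)) for (i in seq_len(nrow(sites))) {
    s <- sites$chars[[i]]
    chars[(sites$start0[i] + 1L):(sites$start0[i] + length(s))] <- s
  }
  paste(chars, collapse = "")
}

## Draw windows until every motif's scan count equals its target.
## Placements are kept across background redraws; if the background never
## verifies, placements are redrawn too.
sample_verified_window <- function(counts_row, pwm_lib, len, gc, profile,
                                   n_outer = 20L, n_inner = 30L) {
  ids <- pwm_ids(pwm_lib)
  site_seqs <- list()
  for (j in seq_along(ids)) {
    cj <- counts_row[j]
    if (cj > 0L) for (r in seq_len(cj)) {
      strand <- sample(c("+", "-"), 1L)
      cons <- strsplit(pwm_consensus(pwm_lib[[j]]), "")[[1]]
      site_seqs[[length(site_seqs) + 1L]] <-
        list(motif_id = ids[j], strand = strand,
             chars = if (strand == "+") cons else revcomp_chars(cons))
    }
  }
  total <- sum(vapply(site_seqs, function(s) length(s$chars), integer(1)))
  if (total > len)
    stop_cref("planted sites cannot fit into the window", "capacity_error")
  for (outer in seq_len(n_outer)) {
    sites <- place_sites(site_seqs, len)
    if (is.null(sites) && length(site_seqs)) next
    for (inner in seq_len(n_inner)) {
      win <- assemble_window(sites, len, gc)
      got <- vapply(pwm_lib, scan_sequence, integer(1),
                    sequence = win, profile = profile)
      if (all(got == counts_row)) {
        return(list(window = win,
                    sites = if (is.null(sites))
                      data.frame(motif_id = character(0),
                                 start0 = integer(0),
                                 strand = character(0))
                    else sites[, c("motif_id", "start0", "strand")]))
      }
    }
  }
  stop_cref("could not sample a hit-free background; use sharper PWMs or stricter thresholds",
            "capacity_error")
}

#' Generate a single-gene promoter fixture with planted motif counts
#'
#' Emits a one-contig genome and a matching annotation whose 1501-bp
#' proximal window (1000 bp upstream through 500 bp downstream of the TSS)
#' contains exactly the requested number of consensus occurrences of each
#' motif — planted on either strand — over a background rejection-sampled
#' to be hit-free at the configured thresholds.
#'
#' @param counts_row Non-negative integer vector of target counts, one per
#'   motif of `pwm_lib` (in library order).
#' @param pwm_lib A `pwm_library`; sharp motifs
#'   ([random_pwm_library()]) keep the rejection sampling fast.
#' @param bg_gc Background GC content in (0, 1).
#' @param seed Integer seed; identical seeds reproduce the fixture.
#' @param profile Threshold profile used for planting verification
#'   (default the stringent `"minFP"`).
#' @param strand Strand of the synthetic gene; on `"-"` the contig holds
#'   the reverse complement of the promoter window.
#' @param gene_id Identifier for the synthetic gene.
#' @return A list with `genome` (`DNAStringSet`), `annotation`
#'   (`GRanges` with gene and mRNA records), `expected` (named count
#'   vector), `sites` (planted site table, 0-based window offsets),
#'   `gene_id` and `chrom`.
#' @export
gen_promoter_fixture <- function(counts_row, pwm_lib, bg_gc = 0.5,
                                 seed = 1L, profile = "minFP",
                                 strand = "+", gene_id = "gene_00001") {
  stopifnot(inherits(pwm_lib, "pwm_library"),
            length(counts_row) == length(pwm_lib),
            all(counts_row >= 0), bg_gc > 0, bg_gc < 1)
  counts_row <- as.integer(counts_row)
  with_seed(seed, {
    res <- sample_verified_window(counts_row, pwm_lib, PROMOTER_LEN,
                                  bg_gc, profile)
    chrom <- paste0("chr_", gene_id)
    if (strand == "+") {
      contig <- res$window
      tss1 <- PROMOTER_UP + 1L                       # 1-based TSS
      gene_start <- tss1; gene_end <- PROMOTER_LEN
    } else {
      contig <- paste(revcomp_chars(strsplit(res$window, "")[[1]]),
                      collapse = "")
      tss1 <- PROMOTER_DOWN + 1L
      gene_start <- 1L; gene_end <- tss1
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(contig, chrom))
    anno <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = rep(gene_start, 2L),
                                end = rep(gene_end, 2L)),
      strand = strand,
      type = c("gene", "mRNA"),
      ID = c(gene_id, paste0(gene_id, ".t1")),
      gene_id = gene_id,
      transcript_id = c(NA_character_, paste0(gene_id, ".t1")))
    names(counts_row) <- pwm_ids(pwm_lib)
    list(genome = genome, annotation = anno, expected = counts_row,
         sites = res$sites, gene_id = gene_id, chrom = chrom)
  })
}

#' Generate a multi-gene genome fixture with planted promoter counts
#'
#' Wraps [gen_promoter_fixture()] for a full genes x motifs target count
#' matrix: one contig per gene, strands alternating, so that
#' [build_cref()] on the returned genome and annotation must reproduce the
#' target matrix exactly.
#'
#' @param count_matrix Non-negative integer matrix, genes x motifs.
#' @inheritParams gen_promoter_fixture
#' @return A list with `genome`, `annotation`, `expected` (the planted
#'   matrix with gene/motif dimnames) and `fixtures` (per-gene site
#'   tables).
#' @export
gen_promoter_genome <- function(count_matrix, pwm_lib, bg_gc = 0.5,
                                seed = 1L, profile = "minFP") {
  count_matrix <- as.matrix(count_matrix)
  g <- nrow(count_matrix)
  gene_ids <- rownames(count_matrix) %||% sprintf("gene_%05d", seq_len(g))
  genomes <- vector("list", g); annos <- vector("list", g)
  fixtures <- vector("list", g)
  for (i in seq_len(g)) {
    fx <- gen_promoter_fixture(count_matrix[i, ], pwm_lib, bg_gc,
                               seed = seed + i,
                               profile = profile,
                               strand = if (i %% 2L) "+" else "-",
                               gene_id = gene_ids[i])
    genomes[[i]] <- fx$genome
    annos[[i]] <- fx$annotation
    fixtures[[i]] <- fx$sites
  }
  expected <- count_matrix
  dimnames(expected) <- list(gene_ids, pwm_ids(pwm_lib))
  list(genome = do.call(c, genomes),
       ## contigs are disjoint across genes, so seqlevels never overlap
       annotation = suppressWarnings(do.call(c, annos)),
       expected = expected,
       fixtures = stats::setNames(fixtures, gene_ids))
}

#' Generate synthetic repeat consensus sequences carrying a planted motif
#' subset
#'
#' Emulates a transposable-element consensus library (Alu/SVA-like): the
#' returned sequences contain at least one consensus occurrence of every
#' planted motif and — after rejection sampling of the background — no hit
#' of any other motif of the library, so that [find_mpa()] must return
#' exactly the planted set.
#'
#' @param pwm_lib A `pwm_library`.
#' @param planted_subset Character vector of motif ids to plant (possibly
#'   empty).
#' @param seed Integer seed.
#' @param profile Threshold profile for verification.
#' @param consensus_len Length of each consensus sequence (repeat
#'   consensus sequences are a few hundred bp).
#' @param motifs_per_seq Planted motifs hosted per sequence.
#' @return A list with `fasta` (`DNAStringSet` of consensus sequences) and
#'   `expected` (the sorted planted id set).
#' @export
gen_repeat_library <- function(pwm_lib, planted_subset, seed = 1L,
                               profile = "minFP", consensus_len = 300L,
                               motifs_per_seq = 4L) {
  stopifnot(inherits(pwm_lib, "pwm_library"))
  ids <- pwm_ids(pwm_lib)
  planted_subset <- as.character(planted_subset)
  if (!all(planted_subset %in% ids))
    stop_cref("planted_subset contains motifs not in the library",
              "pwm_error")
  with_seed(seed, {
    n_seqs <- max(1L, ceiling(length(planted_subset) / motifs_per_seq))
    assign_seq <- if (length(planted_subset))
      rep(seq_len(n_seqs), length.out = length(planted_subset))
    else integer(0)
    seqs <- character(n_seqs)
    for (sq in seq_len(n_seqs)) {
      members <- planted_subset[assign_seq == sq]
      counts_row <- as.integer(ids %in% members)
      sub <- sample_verified_window(counts_row, pwm_lib, consensus_len,
                                    gc = 0.5, profile = profile)
      seqs[sq] <- sub$window
    }
    fasta <- Biostrings::DNAStringSet(
      stats::setNames(seqs, sprintf("REPEAT_SYN_%02d", seq_len(n_seqs))))
    list(fasta = fasta, expected = sort(planted_subset))
  })
}
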