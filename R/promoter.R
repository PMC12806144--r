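## Promoter window selection and CREF matrix assembly.
##
## Conventions: genome coordinates are handled internally as 0-based
## half-open intervals; annotations (GFF3/GTF) are 1-based inclusive and
## converted on input/output. The proximal window covers 1000 bp upstream
## of the TSS through 500 bp downstream, including the TSS base itself
## (1000 + 1 + 500 = 1501 bp), in transcription orientation.

PROMOTER_UP <- 1000L
PROMOTER_DOWN <- 500L
PROMOTER_LEN <- PROMOTER_UP + 1L + PROMOTER_DOWN

## Normalize an annotation (a GFF3/GTF path or a GRanges from
## rtracklayer::import) into a transcript table with 1-based inclusive
## coordinates: gene_id, transcript_id, chrom, start, end, strand.
annotation_transcripts <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- rtracklayer::import(annotation)
  if (is.data.frame(annotation)) return(annotation)
  stopifnot(methods::is(annotation, "GRanges"))
  mc <- S4Vectors::mcols(annotation)
  type <- as.character(mc$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- annotation[is_tx]
  mctx <- S4Vectors::mcols(tx)
  gene_id <- if (!is.null(mctx$gene_id)) as.character(mctx$gene_id) else {
    parent <- mctx$Parent
    vapply(as.list(parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  }
  tx_id <- if (!is.null(mctx$transcript_id)) as.character(mctx$transcript_id)
           else if (!is.null(mctx$ID)) as.character(mctx$ID)
           else sprintf("tx_%06d", seq_along(tx))
  data.frame(gene_id = gene_id,
             transcript_id = tx_id,
             chrom = as.character(GenomicRanges::seqnames(tx)),
             start = GenomicRanges::start(tx),
             end = GenomicRanges::end(tx),
             strand = as.character(GenomicRanges::strand(tx)),
             stringsAsFactors = FALSE)
}

## Gene ids in annotation order (gene features if present, otherwise the
## order of first appearance among transcripts).
annotation_genes <- function(annotation) {
  gr <- if (is.character(annotation) && length(annotation) == 1L)
    rtracklayer::import(annotation) else annotation
  if (methods::is(gr, "GRanges")) {
    type <- as.character(S4Vectors::mcols(gr)$type)
    genes <- gr[type == "gene"]
    if (length(genes)) {
      mcg <- S4Vectors::mcols(genes)
      ids <- if (!is.null(mcg$gene_id)) as.character(mcg$gene_id)
             else as.character(mcg$ID)
      return(ids)
    }
    tx <- annotation_transcripts(gr)
    return(unique(tx$gene_id))
  }
  unique(annotation$gene_id)
}

#' Select the transcription start site of a gene
#'
#' When a gene has multiple annotated transcripts, the start position of
#' the most upstream transcript toward the 5' end is chosen as the TSS: the
#' minimum transcript start on the plus strand, the maximum transcript end
#' on the minus strand. Ties between transcripts are broken by
#' lexicographic transcript id (only the recorded transcript differs).
#'
#' @param transcripts A data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `end` (1-based inclusive, GFF-style) and `strand`, holding
#'   all transcripts of one gene.
#' @return A list with `tss` (1-based coordinate), `strand`, `chrom` and
#'   the `transcript_id` that defined the TSS.
#' @export
select_tss <- function(transcripts) {
  if (nrow(transcripts) == 0L)
    stop_cref("gene has no annotated transcripts", "missing_transcript_error")
  if (length(unique(transcripts$chrom)) != 1L ||
      length(unique(transcripts$strand)) != 1L)
    stop_cref("transcripts of one gene must share chrom and strand",
              "annotation_error")
  strand <- transcripts$strand[1]
  if (!strand %in% c("+", "-"))
    stop_cref("strand must be '+' or '-'", "annotation_error")
  pos <- if (strand == "+") transcripts$start else transcripts$end
  best <- if (strand == "+") min(pos) else max(pos)
  cand <- transcripts$transcript_id[pos == best]
  list(tss = best, strand = strand, chrom = transcripts$chrom[1],
       transcript_id = sort(cand)[1])
}

#' Extract the proximal promoter window around a TSS
#'
#' On the plus strand the window is the 0-based half-open interval
#' `[tss - 1000, tss + 501)`; on the minus strand it is
#' `[tss - 500, tss + 1001)` reverse-complemented, so that the returned
#' sequence always reads 5' to 3' in transcription orientation and has
#' length 1501 unless clipped at a contig edge.
#'
#' @param genome A `DNAStringSet` (or path to a FASTA file).
#' @param chrom Contig name.
#' @param tss 0-based TSS coordinate on the contig.
#' @param strand `"+"` or `"-"`.
#' @return A list with `region` (gene-less promoter record: chrom, 0-based
#'   half-open `start`/`end`, strand, tss, `clipped` flag) and `seq` (a
#'   `DNAString` in transcription orientation).
#' @export
extract_promoter <- function(genome, chrom, tss, strand) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!chrom %in% names(genome))
    stop_cref(sprintf("contig '%s' not in genome", chrom), "coordinate_error")
  clen <- Biostrings::width(genome[chrom])
  if (tss < 0L || tss >= clen)
    stop_cref("TSS outside contig", "coordinate_error")
  if (strand == "+") {
    start0 <- tss - PROMOTER_UP
    end0 <- tss + PROMOTER_DOWN + 1L
  } else if (strand == "-") {
    start0 <- tss - PROMOTER_DOWN
    end0 <- tss + PROMOTER_UP + 1L
  } else stop_cref("strand must be '+' or '-'", "annotation_error")
  clipped <- start0 < 0L || end0 > clen
  start0 <- max(start0, 0L)
  end0 <- min(end0, clen)
  s <- Biostrings::subseq(genome[[chrom]], start = start0 + 1L, end = end0)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  list(region = list(chrom = chrom, start = start0, end = end0,
                     strand = strand, tss = tss, clipped = clipped),
       seq = s)
}

#' Build a CREF matrix from a genome, an annotation and a PWM library
#'
#' For every gene the TSS is selected ([select_tss()]), the 1501-bp
#' proximal window extracted ([extract_promoter()]) and every motif of the
#' library counted on both strands ([scan_sequence()]). Genes whose TSS
#' cannot be resolved (no transcripts, inconsistent annotation, or TSS
#' outside its contig) are dropped and recorded in the `dropped` attribute.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param annotation `GRanges` (from [rtracklayer::import()]), GFF3/GTF
#'   path, or a transcript data.frame with a `gene_id` column.
#' @param pwm_lib A `pwm_library`.
#' @param profile Threshold profile passed to [scan_sequence()].
#' @param species Species tag for the resulting matrix.
#' @return A `cref_matrix` with genes in annotation order and motifs in
#'   library order. Attributes: `dropped` (character vector of dropped
#'   gene ids), `regions` (data.frame of promoter windows, 0-based
#'   half-open).
#' @export
build_cref <- function(genome, annotation, pwm_lib, profile = "minFN",
                       species = "unknown") {
  stopifnot(inherits(pwm_lib, "pwm_library"))
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  tx <- annotation_transcripts(annotation)
  gene_order <- annotation_genes(annotation)
  if (!length(intersect(unique(tx$chrom), names(genome))))
    stop_cref("annotation contigs and genome contigs do not intersect",
              "input_error")
  motif_ids <- pwm_ids(pwm_lib)
  rows <- list(); regions <- list(); dropped <- character(0)
  for (g in gene_order) {
    gt <- tx[tx$gene_id == g, , drop = FALSE]
    res <- tryCatch({
      sel <- select_tss(gt)
      prom <- extract_promoter(genome, sel$chrom, sel$tss - 1L, sel$strand)
      counts <- vapply(pwm_lib, scan_sequence, integer(1),
                       sequence = prom$seq, profile = profile)
      list(counts = as.integer(counts), region = prom$region)
    }, crefdual_error = function(e) NULL)
    if (is.null(res)) { dropped <- c(dropped, g); next }
    rows[[g]] <- res$counts
    regions[[g]] <- data.frame(gene_id = g, chrom = res$region$chrom,
                               start = res$region$start,
                               end = res$region$end,
                               strand = res$region$strand,
                               tss = res$region$tss,
                               clipped = res$region$clipped)
  }
  if (!length(rows))
    stop_cref("no gene promoter could be resolved", "input_error")
  counts <- do.call(rbind, rows)
  colnames(counts) <- motif_ids
  out <- cref_matrix(counts, gene_ids = names(rows), motif_ids = motif_ids,
                     species = species)
  attr(out, "dropped") <- dropped
  attr(out, "regions") <- do.call(rbind, c(regions,
                                           list(make.row.names = FALSE)))
  if (length(dropped))
    message(sprintf("build_cref: dropped %d gene(s) with unresolvable TSS",
                    length(dropped)))
  out
}
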