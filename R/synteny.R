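#' Construct a genomic interval
#'
#' Intervals are 0-based, half-open (`[start, end)`), the BED convention.
#'
#' @param chrom Chromosome name.
#' @param start,end Non-negative integers with `start < end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return List of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (start < 0 || end <= start) stop("need 0 <= start < end")
  if (!strand %in% c("+", "-", ".")) stop("strand must be +, - or .")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "genomic_interval")
}

.validate_chain <- function(ch, where = "chain") {
  b <- ch$blocks
  if (any(b$size <= 0) || any(b$dt < 0) || any(b$dq < 0)) {
    stop(where, ": block sizes must be positive and gaps non-negative")
  }
  if (sum(b$size) + sum(b$dt) != ch$t_end - ch$t_start) {
    stop(where, ": blocks + target gaps do not sum to the target span")
  }
  if (sum(b$size) + sum(b$dq) != ch$q_end - ch$q_start) {
    stop(where, ": blocks + query gaps do not sum to the query span")
  }
  invisible(ch)
}

#' Parse a UCSC chain file
#'
#' Reads pairwise-alignment chains (the format used by the UCSC liftOver
#' tool): a `chain` header per alignment followed by `size dt dq` block
#' lines and a terminal bare block size. Chains map *target* (source
#' assembly) coordinates to *query* (destination assembly) coordinates;
#' query coordinates of minus-strand chains are in reversed-strand space.
#'
#' @param path Chain file path.
#' @return List of class `chain_map`; each element carries the header fields
#'   (`score`, `t_name`, `t_size`, `t_start`, `t_end`, `q_name`, `q_size`,
#'   `q_strand`, `q_start`, `q_end`, `id`) and a `blocks` data.frame with
#'   columns `size`, `dt`, `dq` (gaps are 0 on the final block).
#' @export
parse_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1; next }
    f <- strsplit(line, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12) {
      stop("malformed chain header at line ", i)
    }
    num <- suppressWarnings(as.numeric(f[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(num)) stop("malformed chain header at line ", i)
    ch <- list(score = num[1],
               t_name = f[3], t_size = num[2], t_strand = f[5],
               t_start = num[3], t_end = num[4],
               q_name = f[8], q_size = num[5], q_strand = f[10],
               q_start = num[6], q_end = num[7],
               id = if (length(f) >= 13) f[13] else NA_character_)
    if (ch$t_strand != "+") stop("target strand must be '+' at line ", i)
    if (!ch$q_strand %in% c("+", "-")) stop("bad query strand at line ", i)
    i <- i + 1
    sizes <- dts <- dqs <- numeric()
    repeat {
      if (i > length(lines)) stop("truncated chain block at line ", i)
      b <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      v <- suppressWarnings(as.numeric(b))
      if (anyNA(v) || !length(v) %in% c(1, 3)) {
        stop("malformed block line at line ", i)
      }
      if (length(v) == 3) {
        if (any(v[2:3] < 0)) stop("negative gap at line ", i)
        sizes <- c(sizes, v[1]); dts <- c(dts, v[2]); dqs <- c(dqs, v[3])
        i <- i + 1
      } else {
        sizes <- c(sizes, v[1]); dts <- c(dts, 0); dqs <- c(dqs, 0)
        i <- i + 1
        break
      }
    }
    ch$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    chains[[length(chains) + 1]] <- .validate_chain(ch, paste0("chain ending line ", i - 1))
  }
  structure(chains, class = "chain_map")
}

#' Write a chain map in UCSC chain format
#'
#' Inverse of [parse_chain()]: writing then re-parsing yields an identical
#' chain map.
#'
#' @param cm `chain_map`.
#' @param path Output path.
#' @export
write_chain <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (ch in cm) {
    .validate_chain(ch)
    hdr <- paste("chain", num(ch$score), ch$t_name, num(ch$t_size),
                 ch$t_strand, num(ch$t_start), num(ch$t_end), ch$q_name,
                 num(ch$q_size), ch$q_strand, num(ch$q_start),
                 num(ch$q_end), if (is.na(ch$id)) "" else ch$id)
    writeLines(trimws(hdr), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1) {
      writeLines(paste(num(b$size[-n]), num(b$dt[-n]), num(b$dq[-n])), con)
    }
    writeLines(c(num(b$size[n]), ""), con)
  }
}

# per-chain block layout: target block starts and query (strand-space)
# block starts
.chain_layout <- function(ch) {
  b <- ch$blocks
  tb <- ch$t_start + c(0, cumsum(b$size + b$dt))[seq_len(nrow(b))]
  qb <- ch$q_start + c(0, cumsum(b$size + b$dq))[seq_len(nrow(b))]
  list(tb = tb, qb = qb, size = b$size)
}

# map the interval through one chain; returns mapped-base count and
# plus-strand query min/max, or NULL if nothing maps
.map_through_chain <- function(iv, ch) {
  if (ch$t_name != iv$chrom) return(NULL)
  lay <- .chain_layout(ch)
  o1 <- pmax(iv$start, lay$tb)
  o2 <- pmin(iv$end, lay$tb + lay$size)
  hit <- o2 > o1
  if (!any(hit)) return(NULL)
  off1 <- o1[hit] - lay$tb[hit]
  off2 <- o2[hit] - lay$tb[hit]
  qs <- lay$qb[hit] + off1   # strand-space, half-open [qs, qe)
  qe <- lay$qb[hit] + off2
  if (ch$q_strand == "-") {
    plus_start <- ch$q_size - qe
    plus_end <- ch$q_size - qs
  } else {
    plus_start <- qs
    plus_end <- qe
  }
  list(mapped = sum(o2[hit] - o1[hit]),
       q_name = ch$q_name,
       q_min = min(plus_start), q_max = max(plus_end),
       flip = ch$q_strand == "-")
}

#' Lift an interval across assemblies through a chain map
#'
#' Maps every base of the interval through the aligned blocks of the chains.
#' The result is the interval spanning the minimum to maximum mapped query
#' position. The interval is rejected (returns NULL) when the mapped
#' fraction of its bases falls below `min_match`, or when its bases map
#' through more than one chain (ambiguous placement; the UCSC liftOver
#' multi-mapping mode is not emulated).
#'
#' @param iv [genomic_interval()] (or list with `chrom`, `start`, `end`,
#'   `strand`).
#' @param cm `chain_map` from [parse_chain()].
#' @param min_match Minimum fraction of bases that must map (default 0.95,
#'   the UCSC liftOver default).
#' @return A `genomic_interval` with an extra `mapped_fraction` field, or
#'   NULL when unmappable.
#' @export
liftover_interval <- function(iv, cm, min_match = 0.95) {
  if (min_match <= 0 || min_match > 1) stop("min_match must lie in (0, 1]")
  hits <- Filter(Negate(is.null), lapply(cm, .map_through_chain, iv = iv))
  if (length(hits) == 0 || length(hits) > 1) return(NULL)
  h <- hits[[1]]
  frac <- h$mapped / (iv$end - iv$start)
  if (frac < min_match) return(NULL)
  strand <- iv$strand %||% "."
  if (strand %in% c("+", "-") && h$flip) strand <- setdiff(c("+", "-"), strand)
  out <- genomic_interval(h$q_name, h$q_min, h$q_max, strand)
  out$mapped_fraction <- frac
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference per-base liftover mapper
#'
#' Maps each base of the interval individually through every chain and
#' applies the same acceptance rules as [liftover_interval()] (minimum
#' mapped fraction, single-chain requirement). This brute-force mapper is
#' the package's independent reference implementation used to validate the
#' block-arithmetic mapper; it is exported so validation can be re-run on
#' arbitrary chain sets.
#'
#' @inheritParams liftover_interval
#' @return Same contract as [liftover_interval()].
#' @export
liftover_bruteforce <- function(iv, cm, min_match = 0.95) {
  if (min_match <= 0 || min_match > 1) stop("min_match must lie in (0, 1]")
  bases <- seq(iv$start, iv$end - 1)
  per_chain <- list()
  for (ci in seq_along(cm)) {
    ch <- cm[[ci]]
    if (ch$t_name != iv$chrom) next
    lay <- .chain_layout(ch)
    qpos <- rep(NA_real_, length(bases))
    for (bi in seq_along(lay$tb)) {
      inb <- bases >= lay$tb[bi] & bases < lay$tb[bi] + lay$size[bi]
      if (any(inb)) {
        qs <- lay$qb[bi] + (bases[inb] - lay$tb[bi])
        qpos[inb] <- if (ch$q_strand == "-") ch$q_size - 1 - qs else qs
      }
    }
    if (any(!is.na(qpos))) {
      per_chain[[length(per_chain) + 1]] <-
        list(q_name = ch$q_name, qpos = qpos[!is.na(qpos)],
             flip = ch$q_strand == "-")
    }
  }
  if (length(per_chain) != 1) return(NULL)
  h <- per_chain[[1]]
  frac <- length(h$qpos) / length(bases)
  if (frac < min_match) return(NULL)
  strand <- iv$strand %||% "."
  if (strand %in% c("+", "-") && h$flip) strand <- setdiff(c("+", "-"), strand)
  out <- genomic_interval(h$q_name, min(h$qpos), max(h$qpos) + 1, strand)
  out$mapped_fraction <- frac
  out
}

#' Intersect lifted intervals with an annotation
#'
#' Reports every (query, annotation) pair sharing at least 1 bp of overlap
#' under half-open interval semantics (BEDTools-intersect behaviour),
#' ignoring strand.
#'
#' @param mapped data.frame of lifted intervals: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param annot data.frame of annotation intervals with the same columns.
#' @return data.frame with columns `query_id`, `annot_id`.
#' @export
intersect_annotations <- function(mapped, annot) {
  empty <- data.frame(query_id = character(), annot_id = character())
  if (nrow(mapped) == 0 || nrow(annot) == 0) return(empty)
  gr_q <- GenomicRanges::GRanges(mapped$chrom,
                                 IRanges::IRanges(mapped$start + 1, mapped$end))
  gr_a <- GenomicRanges::GRanges(annot$chrom,
                                 IRanges::IRanges(annot$start + 1, annot$end))
  ov <- GenomicRanges::findOverlaps(gr_q, gr_a, ignore.strand = TRUE)
  out <- data.frame(query_id = mapped$gene_id[S4Vectors::queryHits(ov)],
                    annot_id = annot$gene_id[S4Vectors::subjectHits(ov)])
  out[order(out$query_id, out$annot_id), , drop = FALSE]
}

#' Read a gene annotation (GTF or BED)
#'
#' GTF input (1-based closed; gene records with a `gene_biotype` or
#' `gene_type` attribute) is converted to the internal 0-based half-open
#' convention; BED passes through.
#'
#' @param path Annotation file (`.gtf` or `.bed`).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gtf$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[is.na(gr$type) | gr$type == "gene"]
    meta <- S4Vectors::mcols(gr)
    biotype <- if ("gene_biotype" %in% names(meta)) meta$gene_biotype
               else if ("gene_type" %in% names(meta)) meta$gene_type
               else NA_character_
    data.frame(gene_id = meta$gene_id,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               biotype = biotype)
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(gene_id = gr$name,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               biotype = NA_character_)
  } else {
    stop("unrecognized annotation format: ", path)
  }
}

#' Write a gene annotation as GTF and/or BED6
#'
#' @param genes data.frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `biotype`.
#' @param gtf_path,bed_path Output paths (either may be NULL).
#' @export
write_gene_annotation <- function(genes, gtf_path = NULL, bed_path = NULL) {
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (!is.null(gtf_path)) {
    attrs <- sprintf('gene_id "%s"; gene_biotype "%s";',
                     genes$gene_id, genes$biotype)
    lines <- paste(genes$chrom, "crosslinc", "gene", num(genes$start + 1),
                   num(genes$end), ".", genes$strand, ".", attrs, sep = "\t")
    writeLines(lines, gtf_path)
  }
  if (!is.null(bed_path)) {
    lines <- paste(genes$chrom, num(genes$start), num(genes$end),
                   genes$gene_id, 0, genes$strand, sep = "\t")
    writeLines(lines, bed_path)
  }
  invisible(NULL)
}

#' Flag genes passing a mean normalized-expression filter
#'
#' A gene passes when its mean size-factor-normalized count across all
#' samples exceeds the threshold strictly ("more than" semantics; a mean of
#' exactly the threshold fails). Genes absent from the matrix are flagged
#' missing rather than raising an error.
#'
#' @param ds ExpressionDataset (typically the human progenitor data).
#' @param gene_ids Genes to test.
#' @param threshold Normalized-count threshold (default 20).
#' @return data.frame: `gene_id`, `mean_norm`, `expressed`, `missing`.
#' @export
human_expression_filter <- function(ds, gene_ids, threshold = 20) {
  sf <- size_factors(ds$counts)
  norm <- sweep(ds$counts, 2, sf, "/")
  idx <- match(gene_ids, rownames(norm))
  mean_norm <- ifelse(is.na(idx), NA_real_, rowMeans(norm)[idx])
  data.frame(gene_id = gene_ids,
             mean_norm = mean_norm,
             expressed = !is.na(mean_norm) & mean_norm > threshold,
             missing = is.na(idx))
}

#' Cross-species expression correlation of syntelog pairs
#'
#' For each (mouse, human) gene pair, the Pearson correlation between the
#' two species' per-cell-type median VST profiles over the shared progenitor
#' panel (HSC, CMP, GMP, CLP by default). A constant profile in either
#' species yields a missing correlation.
#'
#' @param mouse_ds,human_ds ExpressionDatasets containing all `cell_types`.
#' @param pairs data.frame with columns `mouse_id`, `human_id`.
#' @param cell_types Cell types entering the profile (>= 2 required).
#' @return `pairs` with a `pearson_r` column appended.
#' @export
correlate_syntelogs <- function(mouse_ds, human_ds, pairs,
                                cell_types = c("HSC", "CMP", "GMP", "CLP")) {
  if (length(unique(cell_types)) < 2) stop("need at least 2 distinct cell types")
  .check_cell_types(mouse_ds, cell_types)
  .check_cell_types(human_ds, cell_types)
  profile <- function(ds) {
    v <- vst(ds$counts, size_factors(ds$counts))
    sapply(cell_types, function(ct) {
      cols <- ds$samples$sample_id[ds$samples$cell_type == ct]
      apply(v[, cols, drop = FALSE], 1, stats::median)
    })
  }
  pm <- profile(mouse_ds)
  ph <- profile(human_ds)
  pairs$pearson_r <- vapply(seq_len(nrow(pairs)), function(i) {
    mi <- match(pairs$mouse_id[i], rownames(pm))
    hi <- match(pairs$human_id[i], rownames(ph))
    if (is.na(mi) || is.na(hi)) return(NA_real_)
    pearson_correlation(pm[mi, ], ph[hi, ])
  }, numeric(1))
  pairs
}

#' Rank candidate syntelog pairs by expression correlation
#'
#' Pairs are ordered by Pearson correlation, descending; pairs with missing
#' correlation sort last; ties break by mouse gene id.
#'
#' @param pairs data.frame with `mouse_id` and `pearson_r` columns.
#' @return The same data.frame, ordered, with a `rank` column.
#' @export
rank_candidates <- function(pairs) {
  if (nrow(pairs) == 0) {
    pairs$rank <- integer(0)
    return(pairs)
  }
  ord <- order(is.na(pairs$pearson_r), -ifelse(is.na(pairs$pearson_r), -Inf,
                                               pairs$pearson_r),
               pairs$mouse_id)
  out <- pairs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
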