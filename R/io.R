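# Plain-text readers/writers for the pipeline's interchange formats.
# Conventions: cytosine tables and BED are 0-based half-open; GTF is 1-based
# inclusive and converted at this boundary.

#' Write / read a cytosine call table (Bismark-extractor-like TSV)
#'
#' Columns: chrom, pos (0-based), strand, context, meth_count, total_count,
#' cell_id, stage.
#' @param calls call table.
#' @param path file path.
#' @export
write_cytosine_tsv <- function(calls, path) {
  data.table::fwrite(data.table::as.data.table(calls), path, sep = "\t")
  invisible(path)
}

#' @rdname write_cytosine_tsv
#' @export
read_cytosine_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("chrom", "strand",
                                                          "context")))
  need <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
  if (!all(need %in% names(dt))) {
    stop("cytosine TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(dt$meth_count > dt$total_count)) {
    stop("invalid cytosine table: meth_count exceeds total_count")
  }
  dt[]
}

#' Write / read BED intervals (0-based half-open)
#'
#' Writes chrom/start/end plus any extra columns after them (BED3+).
#' @param intervals data.frame with chrom, start, end (+ extras).
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  first <- c("chrom", "start", "end")
  rest <- setdiff(names(intervals), first)
  data.table::fwrite(data.table::as.data.table(intervals)[,
    c(first, rest), with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names names for columns beyond chrom/start/end.
#' @export
read_bed <- function(path, col_names = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  base <- c("chrom", "start", "end")
  extra <- if (is.null(col_names)) {
    if (ncol(dt) > 3L) sprintf("V%d", seq_len(ncol(dt) - 3L)) else character(0)
  } else col_names
  data.table::setnames(dt, c(base, extra)[seq_len(ncol(dt))])
  dt[]
}

#' Write DMRs as BED6+
#'
#' name = context, score = -10 log10(q) (capped at 1000), strand ".", then
#' level_A, level_B, delta, direction.
#' @param dmrs [call_dmrs()] output.
#' @param path file path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(round(-10 * log10(pmax(dmrs$q, 1e-100))), 1000)
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = dmrs$context, score = score, strand = ".",
                    level_A = dmrs$level_A, level_B = dmrs$level_B,
                    delta = dmrs$delta, direction = dmrs$direction,
                    stringsAsFactors = FALSE)
  write_bed(bed, path)
}

#' Read a DMR BED6+ written by [write_dmr_bed()]
#' @param path file path.
#' @export
read_dmr_bed <- function(path) {
  dt <- read_bed(path, col_names = c("context", "score", "strand",
                                     "level_A", "level_B", "delta",
                                     "direction"))
  dt$q <- 10^(-dt$score / 10)
  as.data.frame(dt)
}

#' Write / read a GTF-like gene annotation
#'
#' Emits gene, exon, five_prime_utr and three_prime_utr features with
#' 1-based inclusive coordinates (converted from the internal 0-based
#' half-open representation) and `gene_id "..."` attributes.
#' @param annotation a `genome_annotation`.
#' @param path file path.
#' @export
write_gtf <- function(annotation, path) {
  line <- function(df, feature, strand_map) {
    if (nrow(df) == 0L) return(character(0))
    sprintf("%s\tmethexpr\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            df$chrom, feature, df$start + 1L, df$end,
            strand_map[df$gene_id], df$gene_id)
  }
  smap <- setNames(annotation$genes$strand, annotation$genes$gene_id)
  lines <- c(line(annotation$genes, "gene", smap),
             line(annotation$exons, "exon", smap),
             line(annotation$utr5, "five_prime_utr", smap),
             line(annotation$utr3, "three_prime_utr", smap))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gtf
#' @param chrom_lengths named lengths; when NULL taken as max feature end
#'   per chromosome.
#' @export
read_gtf <- function(path, chrom_lengths = NULL) {
  raw <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    col.names = c("chrom", "source", "feature", "start1",
                                  "end1", "score", "strand", "frame",
                                  "attr"),
                    stringsAsFactors = FALSE)
  raw$gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", raw$attr)
  raw$start <- raw$start1 - 1L           # to 0-based half-open
  raw$end <- raw$end1
  pick <- function(feat, cols) {
    d <- raw[raw$feature == feat, cols, drop = FALSE]
    rownames(d) <- NULL
    d
  }
  genes <- pick("gene", c("gene_id", "chrom", "strand", "start", "end"))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(raw$end, raw$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths),
                              names(chrom_lengths))
  }
  structure(list(
    genes = genes,
    exons = pick("exon", c("gene_id", "chrom", "start", "end")),
    utr5 = pick("five_prime_utr", c("gene_id", "chrom", "start", "end")),
    utr3 = pick("three_prime_utr", c("gene_id", "chrom", "start", "end")),
    repeats = data.frame(chrom = character(), start = integer(),
                         end = integer(), family = character(),
                         stringsAsFactors = FALSE),
    accessible = data.frame(chrom = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE),
    chrom_lengths = chrom_lengths,
    genome = NULL
  ), class = "genome_annotation")
}

#' Write / read a count matrix with gene lengths and stage map
#'
#' The counts TSV holds gene_id, length, then one column per cell; the stage
#' map TSV holds cell_id and stage.
#' @param cm a [count_matrix()].
#' @param counts_path,stages_path file paths.
#' @export
write_counts_tsv <- function(cm, counts_path, stages_path) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = cm$gene_lengths[rownames(cm$counts)],
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, counts_path, sep = "\t")
  data.table::fwrite(data.frame(cell_id = names(cm$cell_stage),
                                stage = unname(cm$cell_stage)),
                     stages_path, sep = "\t")
  invisible(counts_path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, stages_path) {
  df <- data.table::fread(counts_path, sep = "\t", data.table = FALSE)
  stg <- data.table::fread(stages_path, sep = "\t", data.table = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, setNames(df$length, df$gene_id),
               setNames(stg$stage, stg$cell_id))
}

#' Write / read PWM files
#'
#' Simple JASPAR-like tab format: a `>id` header line followed by four rows
#' `A<TAB>p1<TAB>p2...` for A, C, G, T base probabilities; several motifs
#' per file allowed.
#' @param pwms named list of [make_pwm()] objects.
#' @param path file path.
#' @export
write_pwm_file <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(pw) {
    c(paste0(">", pw$id),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste(c(b, format(pw$mat[b, ], digits = 10)), collapse = "\t")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm_file
#' @export
read_pwm_file <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    id <- sub("^>\\s*", "", lines[h])
    block <- lines[(h + 1):(h + 4)]
    rows <- lapply(strsplit(block, "\t"), function(x) as.numeric(x[-1]))
    mat <- do.call(rbind, rows)
    out[[id]] <- make_pwm(id, mat)
  }
  out
}

#' Write / read gene sets (two-column TSV: set, gene_id)
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @export
write_gene_sets <- function(sets, path) {
  df <- data.frame(
    set = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  split(df$gene_id, df$set)
}
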