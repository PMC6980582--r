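# File format readers/writers and the coordinate convention.
#
# All coordinates inside the package are 0-based half-open [start, end).
# Conversion to/from 1-based inclusive happens only here, at the I/O boundary.

#' Read a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a named character vector of
#' sequences. Whitespace inside sequence lines is stripped; record order is
#' preserved. Malformed input raises an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no FASTA header in ", path)
  first_hdr <- which(hdr)[1]
  if (any(nzchar(trimws(lines[seq_len(first_hdr - 1)]))))
    stop("sequence data before first header at line ",
         which(nzchar(trimws(lines[seq_len(first_hdr - 1)])))[1])
  ids <- sub("^>([^ \t]*).*$", "\\1", lines[hdr])
  bad <- which(hdr)[!nzchar(ids)]
  if (length(bad)) stop("malformed FASTA header (empty id) at line ", bad[1])
  grp <- cumsum(hdr)
  seq_lines <- gsub("[ \t\r]", "", lines)
  seq_lines[hdr] <- ""
  seqs <- vapply(split(seq_lines[grp > 0], grp[grp > 0]),
                 paste0, character(1), collapse = "")
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record '", ids[which(empty)[1]],
         "' (header at line ", which(hdr)[which(empty)[1]], ")")
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Gene model container
#'
#' Bundles gene spans with their exon and CDS structure. All coordinates are
#' 0-based half-open. Exons of one gene must be sorted and non-overlapping;
#' CDS intervals must lie within the exon union.
#'
#' @param genes data.frame with columns gene_id, scaffold, start, end, strand.
#' @param exons data.frame with columns gene_id, start, end.
#' @param cds data.frame with columns gene_id, start, end.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, exons, cds) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "scaffold", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stop("invalid gene interval (need 0 <= start < end)")
  for (tab in list(exons, cds)) {
    stopifnot(all(c("gene_id", "start", "end") %in% names(tab)))
    if (any(tab$end <= tab$start)) stop("invalid interval (end <= start)")
    if (!all(tab$gene_id %in% genes$gene_id))
      stop("feature references unknown gene: ",
           setdiff(tab$gene_id, genes$gene_id)[1])
  }
  ex <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  ov <- unlist(lapply(split(seq_len(nrow(ex)), ex$gene_id), function(i) {
    if (length(i) < 2) return(FALSE)
    any(ex$start[i][-1] < ex$end[i][-length(i)])
  }))
  if (any(ov)) stop("overlapping exons within gene: ", names(ov)[ov][1])
  structure(list(genes = genes,
                 exons = ex,
                 cds = cds[order(cds$gene_id, cds$start), , drop = FALSE]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", nrow(x$genes), " genes, ", nrow(x$exons), " exons, ",
      nrow(x$cds), " CDS intervals on ",
      length(unique(x$genes$scaffold)), " scaffold(s)\n", sep = "")
  invisible(x)
}

#' Number of genes in a gene_set
#' @param gs A `gene_set`.
#' @export
n_genes <- function(gs) nrow(gs$genes)

# Parse the attribute column of one GFF3 line into a named character vector.
parse_gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else "", ""),
                  vapply(kv, `[`, "", 1))
}

#' Read gene models from GFF3
#'
#' Supports `gene`, `mRNA`, `exon` and `CDS` features linked by `ID`/`Parent`
#' attributes. GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. When a gene carries several mRNAs only the
#' first is used for the exon/CDS structure.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_set].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GFF3 line ", keep[which(nf != 9)[1]], ": expected 9 columns")
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  type <- m[, 3]
  sel <- type %in% c("gene", "mRNA", "exon", "CDS")
  m <- m[sel, , drop = FALSE]
  lineno <- keep[sel]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) stop("non-numeric coordinates at line ", lineno[bad[1]])
  attrs <- lapply(m[, 9], parse_gff3_attrs)
  ids <- vapply(attrs, function(a) if ("ID" %in% names(a)) a[["ID"]] else "", "")
  parents <- vapply(attrs, function(a) if ("Parent" %in% names(a)) a[["Parent"]] else "", "")
  type <- m[, 3]

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  gene_ids <- ids[is_gene]
  if (any(!nzchar(gene_ids))) stop("gene without ID attribute at line ",
                                   lineno[is_gene][!nzchar(gene_ids)][1])
  genes <- data.frame(gene_id = gene_ids,
                      scaffold = m[is_gene, 1],
                      start = start1[is_gene] - 1L,
                      end = end1[is_gene],
                      strand = m[is_gene, 7],
                      stringsAsFactors = FALSE)

  # mRNA -> gene map; features may also point straight at a gene
  mrna2gene <- stats::setNames(parents[type == "mRNA"], ids[type == "mRNA"])
  keep_mrna <- !duplicated(mrna2gene)  # first mRNA per gene wins
  primary <- names(mrna2gene)[keep_mrna]
  resolve_gene <- function(parent, line) {
    if (parent %in% genes$gene_id) return(parent)
    if (parent %in% names(mrna2gene)) {
      g <- mrna2gene[[parent]]
      if (!g %in% genes$gene_id)
        stop("feature at line ", line, " has Parent mRNA '", parent,
             "' whose gene '", g, "' is missing")
      if (!parent %in% primary) return(NA_character_)  # non-primary transcript
      return(g)
    }
    stop("feature at line ", line, " references missing Parent '", parent, "'")
  }
  collect <- function(which_type) {
    idx <- which(type == which_type)
    if (!length(idx))
      return(data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    g <- mapply(resolve_gene, parents[idx], lineno[idx])
    ok <- !is.na(g)
    data.frame(gene_id = unname(g[ok]), start = start1[idx][ok] - 1L,
               end = end1[idx][ok], stringsAsFactors = FALSE)
  }
  gene_set(genes, collect("exon"), collect("CDS"))
}

#' Write gene models to GFF3
#'
#' @param gs A [gene_set].
#' @param path Output path.
#' @export
write_gff3 <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- gs$genes
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    row <- function(type, s, e, attr)
      paste(g$scaffold[i], "tegenome", type, s + 1L, e, ".", g$strand[i], ".",
            attr, sep = "\t")
    writeLines(row("gene", g$start[i], g$end[i], paste0("ID=", id)), con)
    mid <- paste0(id, ".t1")
    writeLines(row("mRNA", g$start[i], g$end[i],
                   paste0("ID=", mid, ";Parent=", id)), con)
    ex <- gs$exons[gs$exons$gene_id == id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(row("exon", ex$start[j], ex$end[j], paste0("Parent=", mid)), con)
    cd <- gs$cds[gs$cds$gene_id == id, , drop = FALSE]
    for (j in seq_len(nrow(cd)))
      writeLines(row("CDS", cd$start[j], cd$end[j], paste0("Parent=", mid)), con)
  }
  invisible(path)
}

#' Construct a repeat annotation table
#'
#' @param scaffold,start,end,strand,family,repeat_class Column vectors;
#'   coordinates 0-based half-open.
#' @return data.frame with an additional `length` column and the superfamily
#'   (part of `repeat_class` after "/", when present).
#' @export
repeat_hits <- function(scaffold, start, end, strand, family, repeat_class) {
  stopifnot(all(end > start), all(nzchar(family)))
  data.frame(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), strand = strand, family = family,
             repeat_class = repeat_class,
             superfamily = ifelse(grepl("/", repeat_class),
                                  sub("^[^/]*/", "", repeat_class), NA_character_),
             length = as.integer(end - start),
             stringsAsFactors = FALSE)
}

#' Read a RepeatMasker .out file
#'
#' Standard layout: two header lines plus a blank line, then whitespace-
#' separated columns (score, divergence, deletion, insertion, query, begin,
#' end, left, strand, repeat name, class/family, ...). 1-based inclusive
#' coordinates are converted to 0-based half-open.
#'
#' @param path Path to a RepeatMasker .out file.
#' @return Repeat table as from [repeat_hits()].
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop the banner: header lines contain non-numeric first tokens / blanks
  body <- which(grepl("^\\s*[0-9]", lines))
  if (!length(body)) {
    return(repeat_hits(character(), integer(), integer(), character(),
                       character(), character())[0, ])
  }
  fields <- strsplit(trimws(lines[body]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed RepeatMasker row at line ", body[which(nf < 11)[1]])
  get <- function(k) vapply(fields, `[`, "", k)
  begin <- suppressWarnings(as.integer(get(6)))
  end <- suppressWarnings(as.integer(get(7)))
  bad <- which(is.na(begin) | is.na(end))
  if (length(bad))
    stop("non-numeric begin/end at line ", body[bad[1]])
  strand <- ifelse(get(9) == "C", "-", get(9))
  repeat_hits(scaffold = get(5), start = begin - 1L, end = end,
              strand = strand, family = get(10), repeat_class = get(11))
}

#' Read a BED-like repeat annotation
#'
#' Six tab-separated columns: scaffold, start, end, family, class, strand,
#' with BED's native 0-based half-open coordinates. This is the dialect the
#' simulator emits.
#'
#' @param path Path to the TSV (a header line starting with "scaffold" is
#'   allowed and skipped).
#' @return Repeat table as from [repeat_hits()].
#' @export
read_repeats_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && startsWith(lines[1], "scaffold")) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(repeat_hits(character(), integer(), integer(), character(),
                       character(), character())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6))
    stop("BED-like repeat row with fewer than 6 columns at line ",
         which(lengths(fields) < 6)[1])
  get <- function(k) vapply(fields, `[`, "", k)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric start/end at line ", which(is.na(start) | is.na(end))[1])
  repeat_hits(get(1), start, end, get(6), get(4), get(5))
}

#' Write a repeat table as BED-like TSV
#' @param rep Repeat table from [repeat_hits()].
#' @param path Output path.
#' @export
write_repeats_bed <- function(rep, path) {
  df <- data.frame(scaffold = rep$scaffold, start = rep$start, end = rep$end,
                   family = rep$family, class = rep$repeat_class,
                   strand = rep$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-keyed TSV table with schema validation
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of mandatory column names
#'   (`gene_id` is always mandatory).
#' @param numeric_cols Columns coerced to numeric; non-numeric entries error.
#' @param allowed Optional named list: column -> vector of allowed values.
#' @return data.frame with unique `gene_id`.
#' @export
read_gene_table <- function(path, required = character(),
                            numeric_cols = character(), allowed = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  need <- union("gene_id", required)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column '", col, "' (gene ",
           df$gene_id[which(is.na(v))[1]], ")")
    df[[col]] <- v
  }
  for (col in names(allowed)) {
    if (!col %in% names(df)) next
    bad <- !df[[col]] %in% allowed[[col]]
    if (any(bad))
      stop("column '", col, "' has value '", df[[col]][bad][1],
           "' outside {", paste(allowed[[col]], collapse = ","), "}")
  }
  df
}

#' Read an FPKM expression table
#'
#' @param path TSV with columns gene_id, hyphae, primordia, fruiting.
#' @return data.frame with numeric, non-negative FPKM columns.
#' @export
read_fpkm_table <- function(path) {
  df <- read_gene_table(path, required = c("hyphae", "primordia", "fruiting"),
                        numeric_cols = c("hyphae", "primordia", "fruiting"))
  if (any(df$hyphae < 0 | df$primordia < 0 | df$fruiting < 0))
    stop("negative FPKM value")
  df
}

#' Write a data.frame as a TSV report ("." for missing values)
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse as
#' numbers become numeric, `true`/`false` become logical.
#'
#' @param path Config file path, or NULL for an empty config.
#' @param defaults Named list merged under the file's values.
#' @return Named list.
#' @export
read_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
                  else val
  }
  cfg
}
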