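#' Read contigs from a FASTA file
#'
#' The header token before the first whitespace becomes the contig id;
#' optional `key=value` tokens in the remainder of the header populate
#' `sample_id` and `assembly_source`. Sequences are upper-cased.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return A data.frame with columns `id`, `sequence`, `sample_id`,
#'   `assembly_source`, `length`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty_contigs())
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  get_token <- function(key) {
    out <- rep(NA_character_, length(headers))
    hit <- grepl(paste0(key, "="), headers)
    out[hit] <- sub(paste0("^.*", key, "="), "",
                    regmatches(headers,
                               regexpr(paste0(key, "=[^[:space:]]+"),
                                       headers)))
    out
  }
  df <- data.frame(id = unname(ids), sequence = unname(seqs),
                   sample_id = get_token("sample"),
                   assembly_source = get_token("source"),
                   stringsAsFactors = FALSE)
  df$length <- nchar(df$sequence)
  df
}

empty_contigs <- function() {
  data.frame(id = character(), sequence = character(),
             sample_id = character(), assembly_source = character(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Write contigs to FASTA
#'
#' Headers carry `sample=` and `source=` tokens when those columns are
#' non-missing, so [read_fasta()] round-trips all metadata.
#'
#' @param contigs contig data.frame (`id`, `sequence`, optional metadata).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  headers <- contigs$id
  if (!is.null(contigs$sample_id)) {
    tok <- ifelse(is.na(contigs$sample_id), "",
                  paste0(" sample=", contigs$sample_id))
    headers <- paste0(headers, tok)
  }
  if (!is.null(contigs$assembly_source)) {
    tok <- ifelse(is.na(contigs$assembly_source), "",
                  paste0(" source=", contigs$assembly_source))
    headers <- paste0(headers, tok)
  }
  ss <- Biostrings::BStringSet(contigs$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

# Required columns per named table schema. Interval columns are 0-based
# half-open throughout.
virocat_schemas <- list(
  evidence = c("contig_id", "virsorter_score", "virfinder_score",
               "pprmeta_score", "refseq_hit_identity", "refseq_hit_coverage",
               "pog_hit_orfs", "checkv_completeness"),
  coverage = c("sample_id", "contig_id", "breadth", "mean_depth",
               "mapped_reads"),
  placements = c("read_id", "contig_id", "start", "end", "strand",
                 "sample_id"),
  lifestyle = c("contig_id", "score"),
  cog = c("contig_id", "category"),
  spacer_map = c("spacer_id", "host_species_id"),
  prophage_intervals = c("genome_id", "start", "end"),
  taxonomy = c("node_id", "parent_id", "rank", "name"),
  hsp = c("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
          "identity", "aligned_len", "strand", "score"),
  truth = c("genome_id", "is_viral", "is_circular", "source_group",
            "cluster_id", "divergence", "lifestyle_score")
)

#' Read a typed TSV table
#'
#' Tab-separated with a header row; lines starting with `#` are comments;
#' the literal string `NA` is a missing value (never coerced to zero).
#'
#' @param path path to the TSV file.
#' @param schema schema name; one of `r paste(names(virocat_schemas),
#'   collapse = ", ")`. Unknown columns are preserved.
#' @return A data.frame.
#' @export
read_table <- function(path, schema) {
  stopifnot(file.exists(path))
  if (!schema %in% names(virocat_schemas)) {
    stop("unknown table schema: '", schema, "'")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- virocat_schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("table ", path, " does not match schema '", schema,
         "'; missing column(s): ", paste(missing_cols, collapse = ", "),
         " (expected header: ", paste(need, collapse = "\t"), ")")
  }
  df
}

#' Write a TSV table
#'
#' Deterministic column order (as given), `#`-prefixed comment lines, `NA`
#' for missing values. All interval columns written by this package are
#' 0-based half-open; the comment header says so.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comment optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write the final catalogue
#'
#' Emits the vOTU FASTA plus one TSV per annotation layer. Every annotation
#' table must have a `contig_id` (or `vc_id`) first column whose contig ids
#' are a subset of the vOTU ids.
#'
#' @param votus contig data.frame of catalogue representatives.
#' @param annotations named list of data.frames; each written to
#'   `<name>.tsv`.
#' @param dir output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_catalogue <- function(votus, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(annotations)) {
    ann <- annotations[[layer]]
    idcol <- intersect(c("contig_id", "vc_id", "virus_id"), names(ann))[1]
    if (is.na(idcol)) {
      stop("annotation layer '", layer, "' lacks an id column")
    }
    if (idcol == "contig_id" && !all(ann$contig_id %in% votus$id)) {
      stop("annotation layer '", layer,
           "' references unknown contig id(s): ",
           paste(setdiff(ann$contig_id, votus$id), collapse = ", "))
    }
  }
  paths <- file.path(dir, "votus.fasta")
  write_fasta(votus, paths)
  for (layer in names(annotations)) {
    p <- file.path(dir, paste0(layer, ".tsv"))
    write_tsv(annotations[[layer]], p,
              comment = "coordinates 0-based half-open")
    paths <- c(paths, p)
  }
  invisible(paths)
}
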