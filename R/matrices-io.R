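# Readers/writers for continuous trait matrices and aligned gene
# fragments, plus supermatrix concatenation with partition bookkeeping.

#' Construct a continuous trait matrix
#'
#' @param values Numeric matrix (taxa in rows, traits in columns).
#' @param taxa Row labels; defaults to `rownames(values)`.
#' @param trait_names Column labels; defaults to `trait_0 .. trait_{k-1}`.
#' @return A numeric matrix with unique row names (class `trait_matrix`).
#' @export
trait_matrix <- function(values, taxa = rownames(values), trait_names = NULL) {
  values <- as.matrix(values)
  if (is.null(taxa)) stopf("trait_matrix: taxa labels required")
  if (anyDuplicated(taxa))
    stopf("trait_matrix: duplicate taxa: %s",
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (is.null(trait_names))
    trait_names <- colnames(values) %||% paste0("trait_", seq_len(ncol(values)) - 1L)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(taxa), trait_names)
  class(values) <- c("trait_matrix", class(values))
  values
}

#' Read a trait CSV (taxon label in first column, one trait per column)
#'
#' Empty cells become missing (`NA`).  Ragged rows and duplicated taxon
#' labels are errors reported with their row number.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `trait_matrix`.
#' @export
read_trait_csv <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L)
    stopf("read_trait_csv: ragged row(s) at line(s) %s of %s",
          paste(which(nf != nf[1]), collapse = ", "), path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("read_trait_csv: no trait columns in %s", path)
  taxa <- trimws(as.character(df[[1]]))
  dup <- which(duplicated(taxa))
  if (length(dup))
    stopf("read_trait_csv: duplicate taxon '%s' at data row %d",
          taxa[dup[1]], dup[1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  trait_matrix(vals, taxa = taxa, trait_names = colnames(df)[-1])
}

#' Write a trait matrix as CSV (full precision round-trip)
#' @param traits A `trait_matrix`.
#' @param path Output path.
#' @export
write_trait_csv <- function(traits, path) {
  txt <- apply(traits, 1:2, function(v) if (is.na(v)) "" else sprintf("%.17g", v))
  df <- data.frame(taxon = rownames(traits), txt, check.names = FALSE)
  colnames(df) <- c("taxon", colnames(traits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a gene alignment
#'
#' @param gene_name Gene label.
#' @param seqs Character matrix (taxa x sites, single characters) or a
#'   named character vector of equal-length sequence strings.
#' @return An object of class `gene_alignment` with fields `gene`, `taxa`,
#'   `seq` (character matrix).
#' @export
gene_alignment <- function(gene_name, seqs) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[which(lens != lens[1])[1]]
      stopf("gene_alignment '%s': unequal sequence length for record '%s'",
            gene_name, bad)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  if (is.null(rownames(seqs))) stopf("gene_alignment: sequences must be named")
  if (ncol(seqs) < 1L) stopf("gene_alignment '%s': zero-length alignment", gene_name)
  structure(list(gene = gene_name, taxa = rownames(seqs),
                 seq = toupper(seqs)),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment '%s': %d taxa x %d sites\n",
              x$gene, length(x$taxa), ncol(x$seq)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Labels are taken from the header line up to the first whitespace;
#' sequences are case-folded to upper case.  Records of unequal length are
#' an error naming the offending record.
#'
#' @param path Path to an aligned FASTA file.
#' @param gene_name Gene label attached to the alignment.
#' @return A `gene_alignment`.
#' @export
read_fasta_alignment <- function(path, gene_name) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stopf("read_fasta_alignment: no FASTA records in %s", path)
  labels <- sub("\\s.*$", "", names(set))
  seqs <- stats::setNames(as.character(set), labels)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stopf("read_fasta_alignment '%s': record '%s' has length %d, expected %d",
          gene_name, labels[which(lens != lens[1])[1]],
          lens[which(lens != lens[1])[1]], lens[1])
  gene_alignment(gene_name, seqs)
}

#' Write a gene alignment as aligned FASTA
#' @param aln A `gene_alignment`.
#' @param path Output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    writeLines(paste(aln$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Concatenate gene alignments (and optionally traits) into a supermatrix
#'
#' Molecular partitions are laid out contiguously in input order; a taxon
#' absent from a gene gets `?` across that gene's range.  When a trait
#' matrix is supplied it becomes one additional continuous partition; taxa
#' absent from it get missing values.
#'
#' @param genes List of `gene_alignment` objects (at least one partition
#'   overall).
#' @param traits Optional `trait_matrix`.
#' @param taxa Optional explicit taxon set; defaults to the union of
#'   partition taxa.
#' @return An object of class `supermatrix` with fields `taxa`,
#'   `partitions` (data frame: name, start, end, type; 0-based half-open),
#'   `mol` (character matrix) and `cont` (numeric matrix or `NULL`).
#' @export
concatenate <- function(genes, traits = NULL, taxa = NULL) {
  if (!length(genes) && is.null(traits))
    stopf("concatenate: no partitions given")
  all_taxa <- unique(c(unlist(lapply(genes, function(g) g$taxa)),
                       if (!is.null(traits)) rownames(traits)))
  taxa <- if (is.null(taxa)) all_taxa else as.character(taxa)
  widths <- vapply(genes, function(g) ncol(g$seq), 0L)
  total <- sum(widths)
  mol <- matrix("?", length(taxa), total, dimnames = list(taxa, NULL))
  parts <- list()
  at <- 0L
  for (g in genes) {
    w <- ncol(g$seq)
    shared <- intersect(taxa, g$taxa)
    if (length(shared))
      mol[shared, (at + 1L):(at + w)] <- g$seq[shared, , drop = FALSE]
    parts[[length(parts) + 1L]] <-
      data.frame(name = g$gene, start = at, end = at + w,
                 type = "molecular", stringsAsFactors = FALSE)
    at <- at + w
  }
  cont <- NULL
  if (!is.null(traits)) {
    cont <- matrix(NA_real_, length(taxa), ncol(traits),
                   dimnames = list(taxa, colnames(traits)))
    shared <- intersect(taxa, rownames(traits))
    cont[shared, ] <- traits[shared, , drop = FALSE]
    parts[[length(parts) + 1L]] <-
      data.frame(name = "traits", start = at, end = at + ncol(traits),
                 type = "continuous", stringsAsFactors = FALSE)
  }
  structure(list(taxa = taxa, partitions = do.call(rbind, parts),
                 mol = mol, cont = cont),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa, %d molecular columns, %d continuous traits\n",
              length(x$taxa), ncol(x$mol),
              if (is.null(x$cont)) 0L else ncol(x$cont)))
  print(x$partitions)
  invisible(x)
}

#' Select a subset of gene alignments by name
#'
#' @param genes List of `gene_alignment` objects.
#' @param gene_names Names to keep; selection preserves the order of
#'   `genes`.
#' @return List of `gene_alignment` objects.
#' @export
subset_genes <- function(genes, gene_names) {
  have <- vapply(genes, function(g) g$gene, "")
  bad <- setdiff(gene_names, have)
  if (length(bad))
    stopf("subset_genes: unknown gene(s): %s", paste(bad, collapse = ", "))
  genes[have %in% gene_names]
}

#' Read a species-to-genus map CSV (columns: species, genus)
#' @param path CSV path.
#' @return Named character vector mapping species to genus.
#' @export
read_genus_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(trimws(df[[2]]), trimws(df[[1]]))
}

#' Write a supermatrix partition table as TSV (0-based half-open ranges)
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_partition_table <- function(sm, path) {
  utils::write.table(sm$partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a supermatrix as relaxed PHYLIP (molecular partitions only)
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), ncol(sm$mol)), con)
  for (i in seq_along(sm$taxa))
    writeLines(sprintf("%s  %s", sm$taxa[i], paste(sm$mol[i, ], collapse = "")),
               con)
  invisible(path)
}

#' Export a supermatrix as a TNT-style file
#'
#' Continuous traits are linearly rescaled to `[0, 1]` per column (the same
#' rescaling the parsimony scorer applies) before writing, so the file can
#' be cross-checked in external parsimony software.
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_tnt <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_cont <- if (is.null(sm$cont)) 0L else ncol(sm$cont)
  writeLines("xread", con)
  writeLines(sprintf("%d %d", ncol(sm$mol) + n_cont, length(sm$taxa)), con)
  if (n_cont) {
    writeLines("&[continuous]", con)
    sc <- rescale_unit(sm$cont)
    for (i in seq_along(sm$taxa)) {
      vals <- ifelse(is.na(sc[i, ]), "?", sprintf("%.3f", sc[i, ]))
      writeLines(sprintf("%s  %s", sm$taxa[i], paste(vals, collapse = " ")), con)
    }
  }
  if (ncol(sm$mol)) {
    writeLines("&[dna]", con)
    for (i in seq_along(sm$taxa))
      writeLines(sprintf("%s  %s", sm$taxa[i],
                         paste(sm$mol[i, ], collapse = "")), con)
  }
  writeLines(";", con)
  invisible(path)
}
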