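# Alignment container and multi-gene curation (occupancy / gene filters,
# concatenation, translation).

GAP <- "-"
MISSING <- "?"

# IUPAC nucleotide symbols (unambiguous first).  U is normalised to T on read.
NUC_CORE <- c("A", "C", "G", "T")
NUC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
AA_CORE <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

alphabet_symbols <- function(alphabet) {
  switch(alphabet,
    nucleotide = c(NUC_CORE, NUC_AMBIG),
    degenerate_nucleotide = c(NUC_CORE, NUC_AMBIG),
    amino_acid = c(AA_CORE, "X"),
    stop("unknown alphabet: ", alphabet)
  )
}

#' Construct a multiple sequence alignment object
#'
#' An alignment is a taxa-by-columns character matrix with a declared
#' alphabet, optional codon structure and a per-gene column partition.
#' Coordinates in `gene_bounds` are 0-based half-open internally; all
#' user-facing messages are 1-based.
#'
#' @param mat character matrix, rows named by taxon.
#' @param alphabet one of `"nucleotide"`, `"degenerate_nucleotide"`,
#'   `"amino_acid"`.
#' @param gene_bounds data.frame with columns `gene`, `start`, `end`
#'   (0-based half-open) partitioning the columns, or `NULL` for a single
#'   anonymous gene spanning everything.
#' @param codon logical; declare codon structure (columns divisible by 3,
#'   every gene interval too).
#' @return object of class `dp_alignment`.
#' @export
alignment <- function(mat, alphabet = "nucleotide", gene_bounds = NULL,
                      codon = FALSE) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("taxon names required as rownames")
  if (is.null(gene_bounds)) {
    gene_bounds <- data.frame(gene = "gene1", start = 0L, end = ncol(mat),
                              stringsAsFactors = FALSE)
  }
  obj <- structure(list(mat = mat, alphabet = alphabet,
                        gene_bounds = gene_bounds, codon = codon,
                        gap = GAP, missing = MISSING),
                   class = "dp_alignment")
  validate_alignment(obj)
  obj
}

validate_alignment <- function(aln) {
  mat <- aln$mat
  ok <- c(alphabet_symbols(aln$alphabet), GAP, MISSING)
  bad <- which(!(mat %in% ok))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(mat))
    stop(sprintf("symbol '%s' not in alphabet '%s' (taxon %s, column %d)",
                 mat[bad[1]], aln$alphabet, rownames(mat)[i[1]], i[2]))
  }
  gb <- aln$gene_bounds
  o <- order(gb$start)
  gb <- gb[o, , drop = FALSE]
  if (nrow(gb)) {
    if (gb$start[1] != 0L || gb$end[nrow(gb)] != ncol(mat) ||
        (nrow(gb) > 1 && any(gb$start[-1] != gb$end[-nrow(gb)])))
      stop("gene_bounds must partition [0, n_columns) without overlap")
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon names: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (aln$codon) {
    if (ncol(mat) %% 3L != 0L)
      stop("codon structure declared but columns not divisible by 3")
    if (any((gb$end - gb$start) %% 3L != 0L))
      stop("codon structure declared but a gene interval length is not divisible by 3")
  }
  invisible(aln)
}

#' @export
print.dp_alignment <- function(x, ...) {
  cat(sprintf("<dp_alignment> %d taxa x %d columns (%s%s), %d gene(s)\n",
              nrow(x$mat), ncol(x$mat), x$alphabet,
              if (x$codon) ", codon" else "", nrow(x$gene_bounds)))
  invisible(x)
}

aln_taxa <- function(aln) rownames(aln$mat)
aln_ncol <- function(aln) ncol(aln$mat)

is_state <- function(mat, aln) !(mat == aln$gap | mat == aln$missing)

#' Read an alignment from FASTA, relaxed PHYLIP or NEXUS
#'
#' @param path file path.
#' @param format `"fasta"`, `"phylip"` (relaxed, sequential or interleaved)
#'   or `"nexus"`.
#' @param alphabet,codon,gene_bounds passed to [alignment()].
#' @return a `dp_alignment` with taxon order as in the file.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                           alphabet = "nucleotide", codon = FALSE,
                           gene_bounds = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- switch(format,
    fasta = parse_fasta(path),
    phylip = parse_phylip(path),
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, function(s) paste(s, collapse = ""))
    })
  lens <- vapply(seqs, nchar, 1L)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment in %s: sequence lengths %s", path,
                 paste(unique(lens), collapse = ", ")))
  mat <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(seqs)
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat[mat == "."] <- GAP
  alignment(mat, alphabet = alphabet, gene_bounds = gene_bounds,
            codon = codon)
}

parse_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- sub("\\s.*$", "", names)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  # headers with no sequence lines would be dropped by split(); detect
  if (length(seqs) != length(names)) stop("FASTA record without sequence in ", path)
  names(seqs) <- names
  as.list(seqs)
}

parse_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) < 2) stop("bad PHYLIP header in ", path)
  ntax <- as.integer(hd[1]); nchar_exp <- as.integer(hd[2])
  body <- lines[-1]
  if (length(body) < ntax) stop("PHYLIP file truncated: ", path)
  first <- body[seq_len(ntax)]
  parts <- lapply(first, function(l) strsplit(trimws(l), "\\s+")[[1]])
  names <- vapply(parts, `[`, "", 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  extra <- body[-seq_len(ntax)]
  if (length(extra)) { # interleaved continuation blocks
    blk <- split(extra, (seq_along(extra) - 1L) %/% ntax)
    for (b in blk) {
      if (length(b) != ntax) stop("interleaved PHYLIP block of wrong size in ", path)
      seqs <- paste0(seqs, vapply(b, function(l) gsub("\\s", "", l), ""))
    }
  }
  got <- unique(nchar(seqs))
  if (length(got) == 1L && !is.na(nchar_exp) && got != nchar_exp)
    stop(sprintf("PHYLIP header declares %d columns but sequences have %d",
                 nchar_exp, got))
  setNames(as.list(seqs), names)
}

#' Write an alignment to FASTA, relaxed PHYLIP or NEXUS
#'
#' @param aln a `dp_alignment`.
#' @param path output path.
#' @param format as in [read_alignment()].
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  switch(format,
    fasta = writeLines(paste0(">", names(seqs), "\n", seqs), path),
    phylip = writeLines(c(sprintf("%d %d", length(seqs), aln_ncol(aln)),
                          sprintf("%s  %s", names(seqs), seqs)), path),
    nexus = {
      x <- lapply(strsplit(seqs, ""), identity)
      names(x) <- names(seqs)
      ape::write.nexus.data(x, path, interleaved = FALSE,
                            format = if (aln$alphabet == "amino_acid")
                              "protein" else "dna")
    })
  invisible(path)
}

#' Drop columns (codons) below a taxon-occupancy threshold
#'
#' Occupancy of a column is the fraction of taxa with a non-gap, non-missing
#' symbol.  For codon-structured data the filter acts on whole codon
#' column-triples (mean occupancy of the triple) so the reading frame is
#' preserved; columns are kept when occupancy is greater than or equal to
#' the threshold.
#'
#' @param aln a `dp_alignment`.
#' @param min_occupancy threshold in (0, 1]; default 0.5.
#' @param per_codon filter whole codons (default: the alignment's codon
#'   flag); set `FALSE` to filter single columns even on codon data.
#' @return filtered `dp_alignment` with recomputed `gene_bounds`.
#' @export
filter_low_occupancy_columns <- function(aln, min_occupancy = 0.5,
                                         per_codon = aln$codon) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  occ <- colMeans(is_state(aln$mat, aln))
  if (per_codon) {
    if (ncol(aln$mat) %% 3L != 0L) stop("per-codon filtering needs in-frame data")
    codon_occ <- colMeans(matrix(occ, nrow = 3))
    keep_codon <- codon_occ >= min_occupancy
    keep <- rep(keep_codon, each = 3)
  } else {
    keep <- occ >= min_occupancy
  }
  if (!any(keep)) stop("all columns filtered at occupancy >= ", min_occupancy)
  subset_columns(aln, which(keep))
}

# Column subset keeping gene bounds consistent (idx sorted, 1-based).
subset_columns <- function(aln, idx) {
  gb <- aln$gene_bounds
  gene_of <- rep(gb$gene, gb$end - gb$start)[idx]
  newmat <- aln$mat[, idx, drop = FALSE]
  counts <- table(factor(gene_of, levels = gb$gene))
  keep_genes <- gb$gene[counts > 0]
  ends <- cumsum(as.integer(counts[counts > 0]))
  gb2 <- data.frame(gene = keep_genes,
                    start = c(0L, head(ends, -1L)), end = ends,
                    stringsAsFactors = FALSE)
  alignment(newmat, alphabet = aln$alphabet, gene_bounds = gb2,
            codon = aln$codon)
}

#' Build a gene table from per-gene alignments
#'
#' A gene table holds one alignment per gene over a shared taxon universe
#' together with per-gene presence flags (a taxon is absent from a gene
#' when its row is entirely missing, or not in that gene's file at all).
#'
#' @param genes named list of `dp_alignment` objects.
#' @param taxa optional taxon universe (default: union over genes, in order
#'   of first appearance).
#' @return object of class `dp_genetable`.
#' @export
gene_table <- function(genes, taxa = NULL) {
  stopifnot(is.list(genes), length(genes) > 0)
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("genes must be a named list")
  alpha <- unique(vapply(genes, `[[`, "", "alphabet"))
  if (length(alpha) != 1) stop("genes with mixed alphabets: ",
                               paste(alpha, collapse = ", "))
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(genes, aln_taxa)))
  }
  pres <- matrix(FALSE, length(taxa), length(genes),
                 dimnames = list(taxa, names(genes)))
  for (g in names(genes)) {
    m <- genes[[g]]$mat
    here <- rownames(m)[rowSums(m != MISSING) > 0L]
    pres[intersect(taxa, here), g] <- TRUE
  }
  structure(list(genes = genes, taxa = taxa, presence = pres,
                 lengths = vapply(genes, aln_ncol, 1L)),
            class = "dp_genetable")
}

#' @export
print.dp_genetable <- function(x, ...) {
  cat(sprintf("<dp_genetable> %d genes, %d taxa, %.1f%% gene sequences missing\n",
              length(x$genes), length(x$taxa), 100 * mean(!x$presence)))
  invisible(x)
}

#' Discard short genes and genes without required-group coverage
#'
#' Keeps genes whose length is at least `min_len_bp` ("under `min_len_bp`"
#' is discarded, so the boundary length is kept) and which have at least one
#' present taxon in every required group.
#'
#' @param table a `dp_genetable`.
#' @param min_len_bp minimum length in columns (bp); default 200.
#' @param required_groups named list mapping group name to character vector
#'   of taxa; each group must have >= 1 present taxon for a gene to pass.
#' @return filtered `dp_genetable` (warns if empty).
#' @export
filter_genes <- function(table, min_len_bp = 200, required_groups = list()) {
  stopifnot(inherits(table, "dp_genetable"), min_len_bp >= 0)
  keep <- table$lengths >= min_len_bp
  for (grp in names(required_groups)) {
    tx <- intersect(required_groups[[grp]], table$taxa)
    if (!length(tx)) { keep[] <- FALSE; next }
    cov <- colSums(table$presence[tx, , drop = FALSE]) > 0
    keep <- keep & cov
  }
  if (!any(keep)) {
    warning("all genes filtered out")
    return(structure(list(genes = list(), taxa = table$taxa,
                          presence = table$presence[, 0, drop = FALSE],
                          lengths = integer(0)),
                     class = "dp_genetable"))
  }
  gene_table(table$genes[keep], taxa = table$taxa)
}

#' Concatenate the genes of a gene table into one alignment
#'
#' Taxa absent from a gene are filled with the missing symbol; the fraction
#' of absent gene-by-taxon cells is attached as attribute
#' `missing_fraction`.
#'
#' @param table a `dp_genetable`.
#' @return a `dp_alignment` with per-gene `gene_bounds`.
#' @export
concatenate <- function(table) {
  stopifnot(inherits(table, "dp_genetable"), length(table$genes) > 0)
  taxa <- table$taxa
  total <- sum(table$lengths)
  mat <- matrix(MISSING, length(taxa), total, dimnames = list(taxa, NULL))
  pos <- 0L
  starts <- integer(length(table$genes))
  for (i in seq_along(table$genes)) {
    g <- table$genes[[i]]
    idx <- pos + seq_len(aln_ncol(g))
    common <- intersect(taxa, aln_taxa(g))
    mat[common, idx] <- g$mat[common, , drop = FALSE]
    starts[i] <- pos
    pos <- pos + aln_ncol(g)
  }
  gb <- data.frame(gene = names(table$genes), start = starts,
                   end = starts + unname(table$lengths),
                   stringsAsFactors = FALSE)
  codon <- all(vapply(table$genes, `[[`, TRUE, "codon"))
  out <- alignment(mat, alphabet = table$genes[[1]]$alphabet,
                   gene_bounds = gb, codon = codon)
  attr(out, "missing_fraction") <- mean(!table$presence)
  out
}

#' Translate a codon alignment to amino acids
#'
#' Gap codons (`---`) become gaps, codons containing a missing symbol (or a
#' mix of gap and state) become missing, ambiguity codons whose compatible
#' expansions encode more than one amino acid become `X`, and any codon
#' unambiguously encoding a stop raises an error naming taxon, gene and
#' codon position (curation is expected to have removed stops).
#'
#' @param aln in-frame codon `dp_alignment` (or a `dp_genetable`, translated
#'   gene by gene).
#' @param genetic_code NCBI translation table number (default 1).
#' @return amino-acid `dp_alignment` (or gene table) with one column per codon.
#' @export
translate_alignment <- function(aln, genetic_code = 1) {
  if (inherits(aln, "dp_genetable")) {
    genes <- lapply(aln$genes, translate_alignment, genetic_code = genetic_code)
    return(gene_table(genes, taxa = aln$taxa))
  }
  stopifnot(inherits(aln, "dp_alignment"),
            aln$alphabet %in% c("nucleotide", "degenerate_nucleotide"))
  if (ncol(aln$mat) %% 3L != 0L) stop("alignment is not in frame")
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  n_codons <- ncol(aln$mat) %/% 3L
  gb <- aln$gene_bounds
  gene_of <- rep(gb$gene, (gb$end - gb$start) %/% 3L)
  out <- matrix(MISSING, nrow(aln$mat), n_codons,
                dimnames = list(rownames(aln$mat), NULL))
  cache <- new.env(parent = emptyenv()) # memoise per codon string
  for (i in seq_len(nrow(aln$mat))) {
    row <- aln$mat[i, ]
    for (j in seq_len(n_codons)) {
      cdn <- row[(3L * j - 2L):(3L * j)]
      key <- paste(cdn, collapse = "")
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- tryCatch(translate_codon(cdn, code), stop_codon = identity)
        cache[[key]] <- hit
      }
      if (inherits(hit, "condition"))
        stop(sprintf("stop codon %s at codon %d of gene %s in taxon %s",
                     key, j, gene_of[j], rownames(aln$mat)[i]))
      out[i, j] <- hit
    }
  }
  gb2 <- data.frame(gene = gb$gene, start = gb$start %/% 3L,
                    end = gb$end %/% 3L, stringsAsFactors = FALSE)
  alignment(out, alphabet = "amino_acid", gene_bounds = gb2, codon = FALSE)
}

translate_codon <- function(cdn, code) {
  if (all(cdn == GAP)) return(GAP)
  if (any(cdn == MISSING) || any(cdn == GAP)) return(MISSING)
  exps <- expand_codon(cdn)
  aas <- unique(unname(code[exps]))
  if (any(is.na(aas))) return(MISSING)
  if (all(aas == "*"))
    stop(structure(class = c("stop_codon", "error", "condition"),
                   list(message = "stop codon", call = NULL)))
  aas <- setdiff(aas, "*")
  if (length(aas) == 1L) aas else "X"
}

# All unambiguous codons compatible with a (possibly ambiguous) codon.
expand_codon <- function(cdn) {
  sets <- lapply(cdn, function(s) strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]])
  ex <- expand.grid(sets, stringsAsFactors = FALSE)
  apply(ex, 1, paste, collapse = "")
}
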