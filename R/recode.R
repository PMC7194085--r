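# Codon-degenerate recoding: replace each codon by the minimal IUPAC
# ambiguity pattern covering its connected synonymous codon family, so that
# synonymous point substitutions become invisible to the likelihood.

# inverse IUPAC lookup: sorted base-set string -> symbol
iupac_cover <- local({
  map <- NULL
  function(bases) {
    if (is.null(map)) {
      m <- Biostrings::IUPAC_CODE_MAP
      map <<- setNames(names(m),
                       vapply(strsplit(m, ""),
                              function(x) paste(sort(x), collapse = ""), ""))
    }
    map[[paste(sort(unique(bases)), collapse = "")]]
  }
})

#' Build a codon degeneracy table for a genetic code
#'
#' For each amino acid, its codons are partitioned into families connected
#' by single-nucleotide synonymous substitutions; every codon in a family
#' is mapped to the same three-symbol IUPAC pattern, the per-position
#' minimal cover of the family.  Under the standard code this yields e.g.
#' all Ala codons -> `GCN`, all six Leu codons -> `YTN` (the two Leu boxes
#' are bridged by TTA-CTA / TTG-CTG), the two Ser families -> `TCN` and
#' `AGY` (not single-substitution connected).  Stop codons map to
#' themselves.
#'
#' @param genetic_code NCBI translation table number (default 1).
#' @return named character vector of class `dp_degen_table`: codon -> pattern.
#' @export
build_degeneracy_table <- function(genetic_code = 1) {
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  codons <- names(code)
  tab <- setNames(character(length(codons)), codons)
  for (aa in unique(code)) {
    fam <- codons[code == aa]
    if (aa == "*") { tab[fam] <- fam; next }
    for (comp in connected_components(fam)) {
      cm <- do.call(rbind, strsplit(comp, ""))
      pat <- paste(vapply(1:3, function(p) iupac_cover(cm[, p]), ""),
                   collapse = "")
      tab[comp] <- pat
    }
  }
  structure(tab, genetic_code = genetic_code, class = "dp_degen_table")
}

# components of the graph on codons with edges = single-position differences
connected_components <- function(codons) {
  n <- length(codons)
  cm <- do.call(rbind, strsplit(codons, ""))
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sum(cm[i, ] != cm[j, ]) == 1L) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  unname(split(codons, comp))
}

#' @export
print.dp_degen_table <- function(x, ...) {
  cat(sprintf("<dp_degen_table> genetic code %s, %d codons -> %d patterns\n",
              attr(x, "genetic_code"), length(x), length(unique(x))))
  invisible(x)
}

#' Write a degeneracy table as TSV for inspection
#' @param table a `dp_degen_table`.
#' @param path output path.
#' @export
write_degeneracy_table <- function(table, path) {
  code <- Biostrings::getGeneticCode(as.character(attr(table, "genetic_code")))
  df <- data.frame(codon = names(table), amino_acid = unname(code[names(table)]),
                   pattern = unname(unclass(table)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Codon-degenerate recoding of a nucleotide alignment
#'
#' Every codon is replaced by its degeneracy pattern.  Codons containing a
#' gap or missing symbol pass through unchanged; codons already containing
#' ambiguity symbols are recoded to the minimal IUPAC cover of the union of
#' the patterns of their compatible sense expansions.  The operation is
#' idempotent.
#'
#' @param aln codon-structured nucleotide `dp_alignment` (or `dp_genetable`).
#' @param table a `dp_degen_table` (default: standard code).
#' @return recoded alignment with alphabet `degenerate_nucleotide`.
#' @export
degen_recode <- function(aln, table = build_degeneracy_table(1)) {
  if (inherits(aln, "dp_genetable")) {
    genes <- lapply(aln$genes, degen_recode, table = table)
    return(gene_table(genes, taxa = aln$taxa))
  }
  stopifnot(inherits(aln, "dp_alignment"),
            aln$alphabet %in% c("nucleotide", "degenerate_nucleotide"))
  if (ncol(aln$mat) %% 3L != 0L) stop("alignment is not in frame")
  cache <- new.env(parent = emptyenv())
  out <- aln$mat
  n_codons <- ncol(out) %/% 3L
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(n_codons)) {
      cols <- (3L * j - 2L):(3L * j)
      cdn <- out[i, cols]
      if (any(cdn == GAP | cdn == MISSING)) next
      key <- paste(cdn, collapse = "")
      pat <- cache[[key]]
      if (is.null(pat)) {
        pat <- recode_codon(cdn, table)
        cache[[key]] <- pat
      }
      out[i, cols] <- pat
    }
  }
  res <- alignment(out, alphabet = "degenerate_nucleotide",
                   gene_bounds = aln$gene_bounds, codon = TRUE)
  res
}

recode_codon <- function(cdn, table) {
  code <- Biostrings::getGeneticCode(as.character(attr(table, "genetic_code")))
  exps <- expand_codon(cdn)
  sense <- exps[code[exps] != "*"]
  if (!length(sense))
    stop(sprintf("codon %s has no sense expansion under the genetic code",
                 paste(cdn, collapse = "")))
  pats <- unique(unname(table[sense]))
  pm <- do.call(rbind, lapply(pats, function(p)
    vapply(strsplit(p, "")[[1]],
           function(s) Biostrings::IUPAC_CODE_MAP[[s]], "")))
  vapply(1:3, function(p)
    iupac_cover(unlist(strsplit(pm[, p], ""))), "")
}
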