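# Codon-level lookup tables shared by the CDS generator and the NG86
# estimator. Built once at load time from the standard genetic code shipped
# with Biostrings.

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  # all single-nucleotide neighbours of each codon and their synonymy
  neigh <- lapply(codons, function(cd) {
    s <- strsplit(cd, "")[[1]]
    out <- list()
    for (p in 1:3) for (b in setdiff(bases, s[p])) {
      t <- s; t[p] <- b
      out[[length(out) + 1L]] <- c(pos = p, alt = paste(t, collapse = ""))
    }
    m <- do.call(rbind, out)
    data.frame(pos = as.integer(m[, "pos"]), alt = m[, "alt"],
               syn = gc[m[, "alt"]] == gc[cd] & gc[cd] != "*",
               stop = gc[m[, "alt"]] == "*",
               stringsAsFactors = FALSE)
  })
  names(neigh) <- codons
  # NG86 synonymous site count per codon: per position, fraction of the three
  # possible changes that are synonymous (changes to stop count as
  # nonsynonymous, so S + N = 3 per codon)
  syn_sites <- vapply(neigh, function(d) sum(d$syn) / 3, numeric(1))
  syn_opts <- lapply(neigh, function(d) d$alt[d$syn])
  codon_env$tab <- list(aa = gc, neigh = neigh, syn_sites = syn_sites,
                        syn_opts = syn_opts,
                        sense = codons[gc != "*"])
  codon_env$tab
}
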