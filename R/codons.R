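# Codon utilities shared by the simulator and the selection statistics.
# The standard genetic code (table 1) is taken from Biostrings and cached.

genetic_code <- function() {
  if (is.null(.riffle_cache$code)) .riffle_cache$code <- Biostrings::GENETIC_CODE
  .riffle_cache$code
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translate_codons <- function(seqs) {
  code <- genetic_code()
  vapply(seqs, function(s) paste(code[split_codons(s)], collapse = ""), "",
         USE.NAMES = TRUE)
}

# Per-codon synonymous/nonsynonymous site counts (pathway method): the
# synonymous fraction at each position is the share of the 3 possible
# single-base changes that preserve the amino acid; changes to stop codons
# count as nonsynonymous. Returns a 2-column matrix indexed by codon.
codon_site_table <- function() {
  if (!is.null(.riffle_cache$sites)) return(.riffle_cache$sites)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  tab <- matrix(NA_real_, nrow = length(code), ncol = 2,
                dimnames = list(names(code), c("syn", "nonsyn")))
  for (cd in sense) {
    ch <- strsplit(cd, "")[[1]]
    syn <- 0
    for (p in 1:3) for (b in BASES[BASES != ch[p]]) {
      alt <- ch; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (code[[alt]] != "*" && code[[alt]] == code[[cd]]) syn <- syn + 1 / 3
    }
    tab[cd, ] <- c(syn, 3 - syn)
  }
  .riffle_cache$sites <- tab
  tab
}

# Synonymous/nonsynonymous difference counts between two codons, averaged
# over all minimal mutational pathways that avoid stop codons (pathways
# through a stop are dropped and the rest re-weighted; if every pathway is
# blocked, all are used). Memoised.
codon_diff <- function(c1, c2) {
  key <- paste0(c1, c2)
  memo <- .riffle_cache$diffs
  if (is.null(memo)) memo <- .riffle_cache$diffs <- new.env(parent = emptyenv())
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  code <- genetic_code()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  res <- if (length(pos) == 0L) {
    c(syn = 0, nonsyn = 0)
  } else {
    paths <- if (length(pos) == 1L) list(pos) else
      apply(gtools_permutations(pos), 1, identity, simplify = FALSE)
    per_path <- lapply(paths, function(ord) {
      cur <- a; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        aa1 <- code[[paste(cur, collapse = "")]]
        aa2 <- code[[paste(nxt, collapse = "")]]
        if (aa2 == "*" || aa1 == "*") return(NULL)  # blocked pathway
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(syn = sd, nonsyn = nd)
    })
    ok <- per_path[!vapply(per_path, is.null, TRUE)]
    if (length(ok) == 0L) {
      # recompute counting through-stop steps as nonsynonymous
      ok <- lapply(paths, function(ord) {
        cur <- a; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur; nxt[p] <- b[p]
          if (code[[paste(cur, collapse = "")]] ==
              code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(syn = sd, nonsyn = nd)
      })
    }
    Reduce(`+`, ok) / length(ok)
  }
  memo[[key]] <- res
  res
}

# all orderings of a small index vector (2 or 3 elements)
gtools_permutations <- function(x) {
  n <- length(x)
  if (n == 2L) return(rbind(x, rev(x)))
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    sub <- gtools_permutations(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}

validate_codon_alignment <- function(seqs) {
  if (length(seqs) < 2L) abort("A codon alignment needs at least 2 sequences.")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("alignment error: sequences differ in length.")
  if (L %% 3L != 0L) abort("Alignment length must be divisible by 3.")
  if (any(grepl("[^ACGT]", seqs))) abort("Only A/C/G/T are allowed.")
  aa <- translate_codons(seqs)
  if (any(grepl("\\*", aa))) abort("Internal stop codon in coding alignment.")
  invisible(seqs)
}
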