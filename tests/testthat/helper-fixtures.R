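## shared in-code fixtures

aln_from <- function(id, kind, ...) {
  ortholog_alignment(id, kind, c(...))
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

## random coding alignment over A,C,G,T,N,- with given dimensions
random_alignment <- function(id, n_species, n_codons, seed,
                             gap_frac = 0.05) {
  set.seed(seed)
  L <- 3L * n_codons
  m <- matrix(sample(c("A", "C", "G", "T"), n_species * L, replace = TRUE),
              n_species, L)
  gaps <- runif(length(m)) < gap_frac
  m[gaps] <- sample(c("-", "N"), sum(gaps), replace = TRUE)
  rownames(m) <- sprintf("sp%02d", seq_len(n_species))
  ortholog_alignment(id, "coding", m)
}

## independent brute-force per-column GC counter (oracle)
naive_gc <- function(aln, cols) {
  vapply(aln$species, function(sp) {
    gc <- 0L; at <- 0L
    for (j in cols) {
      ch <- aln$matrix[sp, j]
      if (ch %in% c("G", "C")) gc <- gc + 1L
      if (ch %in% c("A", "T")) at <- at + 1L
    }
    c(gc = gc, counted = gc + at)
  }, integer(2))
}

## independent recursive PIC (oracle): returns standardized contrasts
naive_pic <- function(phy, x) {
  n <- length(phy$tip.label)
  val <- c(x[phy$tip.label], rep(NA_real_, phy$Nnode))
  elen <- setNames(phy$edge.length, phy$edge[, 2])
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  contrasts <- numeric(0)
  extra <- setNames(numeric(n + phy$Nnode), seq_len(n + phy$Nnode))
  recurse <- function(nd) {
    ch <- kids[[as.character(nd)]]
    if (is.null(ch)) return(invisible(NULL))
    for (c1 in ch) recurse(c1)
    v <- elen[as.character(ch)] + extra[as.character(ch)]
    contrasts <<- c(contrasts, (val[ch[1]] - val[ch[2]]) / sqrt(sum(v)))
    val[nd] <<- (val[ch[1]] / v[1] + val[ch[2]] / v[2]) / (1 / v[1] + 1 / v[2])
    extra[as.character(nd)] <<- prod(v) / sum(v)
    invisible(NULL)
  }
  recurse(n + 1L)
  contrasts
}

## species tree + per-branch theta helpers for small simulations
flat_theta <- function(theta, tips) {
  matrix(theta, 1, length(tips), dimnames = list(NULL, tips))
}
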