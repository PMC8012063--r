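# Small deterministic fixtures built in code.

make_panel <- function(genes = c("A", "B", "C", "D"),
                       tissues = c("liver", "skin"),
                       p = NULL, fc = NULL, ex = NULL) {
  dn <- list(genes, tissues)
  if (is.null(p))
    p <- matrix(seq(0.05, 0.9, length.out = length(genes) * length(tissues)),
                length(genes), dimnames = dn)
  else dimnames(p) <- dn
  if (is.null(fc))
    fc <- matrix(rep(c(1, -1), length.out = length(genes) * length(tissues)),
                 length(genes), dimnames = dn)
  else dimnames(fc) <- dn
  if (is.null(ex))
    ex <- matrix(10, length(genes), length(tissues), dimnames = dn)
  else dimnames(ex) <- dn
  TissuePanel(p = p, log2fc = fc, meanExpr = ex)
}

write_de_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# TOM with prescribed off-diagonal values (validity-checked container).
make_tom <- function(tm, beta = 26) {
  if (is.null(rownames(tm)))
    rownames(tm) <- colnames(tm) <- paste0("g", seq_len(nrow(tm)))
  new("TOMatrix", tom = tm, beta = beta, corType = "test")
}

# Independent brute-force TOM oracle: triple loop over the published
# signed-TOM definition.
tom_bruteforce <- function(corr, beta) {
  n <- nrow(corr)
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    num <- a[i, j]
    for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
    num <- num - a[i, i] * a[i, j] - a[i, j] * a[j, j]  # diag excluded (0 anyway)
    ki <- sum(a[i, ]); kj <- sum(a[j, ])
    tom[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(corr)
  tom
}
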