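# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package code paths they check.

# brute-force ORF scan: for every sense frame and every ATG, walk codon by
# codon to the first in-frame stop; keep, per stop, the longest span
brute_force_orfs <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (f in 0:2) {
    starts <- c()
    i <- 1L + f
    while (i + 2L <= n) {
      if (substr(s, i, i + 2L) == "ATG") starts <- c(starts, i)
      i <- i + 3L
    }
    for (st in starts) {
      j <- st
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        if (j > st && cod %in% stops) {
          key <- paste(f, j)
          len <- j + 2L - st + 1L
          if (is.null(found[[key]]) || found[[key]]["len"] < len)
            found[[key]] <- c(start = st, end = j + 2L, frame = f, len = len)
          break
        }
        j <- j + 3L
      }
    }
  }
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length_nt = integer(0)))
  m <- do.call(rbind, found)
  out <- data.frame(start = m[, "start"], end = m[, "end"],
                    frame = m[, "frame"], length_nt = m[, "len"])
  out <- out[order(-out$length_nt, out$start, out$frame), ]
  rownames(out) <- NULL
  out
}

# naive PCIT: literal triple loop over ordered trios with the published
# tolerance rule; written independently of the compiled implementation
naive_pcit_edges <- function(r) {
  n <- nrow(r)
  pc <- function(rxy, rxz, ryz) {
    den <- (1 - rxz^2) * (1 - ryz^2)
    if (den < 1e-12) return(rxy)
    (rxy - rxz * ryz) / sqrt(den)
  }
  keep <- matrix(TRUE, n, n)
  for (x in 1:n) for (y in 1:n) {
    if (x == y) next
    for (z in 1:n) {
      if (z == x || z == y) next
      ratio <- function(rab, raz, rbz)
        if (rab == 0) 0 else pc(rab, raz, rbz) / rab
      tol <- (ratio(r[x, y], r[x, z], r[y, z]) +
              ratio(r[x, z], r[x, y], r[y, z]) +
              ratio(r[y, z], r[x, y], r[x, z])) / 3
      if (abs(r[x, y]) < abs(tol * r[x, z]) &&
          abs(r[x, y]) < abs(tol * r[y, z])) {
        keep[x, y] <- keep[y, x] <- FALSE
        break
      }
    }
  }
  ids <- rownames(r)
  out <- data.frame(gene_a = character(0), gene_b = character(0))
  for (x in 1:(n - 1)) for (y in (x + 1):n)
    if (keep[x, y])
      out <- rbind(out, data.frame(gene_a = min(ids[x], ids[y]),
                                   gene_b = max(ids[x], ids[y])))
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# random nucleotide string
rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random edge set over a node universe
rand_edges <- function(nodes, n_edges) {
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  data.frame(gene_a = a[keep], gene_b = b[keep], r = runif(sum(keep), -1, 1))
}

# small hand-built reference annotation used by the classifier tests:
# one 3-exon gene on each strand
toy_reference <- function() {
  transcript_models(data.frame(
    transcript_id = rep(c("R1.1", "R2.1"), each = 3),
    gene_id = rep(c("R1", "R2"), each = 3),
    chrom = "chr1",
    strand = rep(c("+", "-"), each = 3),
    start = c(10000, 11000, 12000, 50000, 51000, 52000),
    end = c(10200, 11200, 12200, 50200, 51200, 52200)))
}

one_tx <- function(id, strand, starts, ends, chrom = "chr1") {
  transcript_models(data.frame(
    transcript_id = id, gene_id = paste0("X_", id), chrom = chrom,
    strand = strand, start = starts, end = ends))
}
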