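# Independent oracles, deliberately naive: a brute-force affine-gap local
# alignment DP and a breadth-first-search components finder. These exist to
# cross-check the package's fast paths and must stay independent of them.

oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Gotoh three-state Smith-Waterman; a gap of length L costs open + L * ext.
# Returns the optimal local score (>= 0; empty alignment allowed).
oracle_local_score <- function(a, b, open = 11, ext = 1) {
  S <- oracle_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[av[i], bv[j]]
      M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Breadth-first-search connected components; returns membership labelled
# like the package does (size-descending, ties by smallest member id).
oracle_components <- function(nodes, from, to) {
  nodes <- sort(nodes)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (s in nodes) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, setdiff(adj[[v]], names(comp)[!is.na(comp)]))
    }
  }
  # canonical renumbering
  sizes <- table(comp)
  firsts <- vapply(split(names(comp), comp), min, character(1))
  o <- order(-as.integer(sizes), firsts)
  ranked <- as.integer(names(sizes))[o]
  setNames(match(comp, ranked), names(comp))
}

random_aa_string <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

# partitions equal up to relabelling
same_partition <- function(p, q) {
  stopifnot(length(p) == length(q))
  length(unique(paste(p, q))) == length(unique(p)) &&
    length(unique(paste(p, q))) == length(unique(q))
}
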