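# Independent reference implementations used to cross-check the package's
# optimized kernels. These deliberately use different machinery (utils::adist,
# brute-force scans) than the code under test.

# substitute `n` random positions of a DNA string
mutate_seq <- function(s, n) {
  if (n == 0) return(s)
  v <- strsplit(s, "")[[1]]
  p <- sample(length(v), n)
  for (i in p) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# greedy centroid clustering oracle: quadratic all-pairs identity via
# utils::adist (Levenshtein), both orientations
oracle_greedy_cluster <- function(seqs, thr) {
  cent <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (c in cent) {
      L <- max(nchar(seqs[i]), nchar(seqs[c]))
      id <- 1 - min(utils::adist(seqs[i], seqs[c]),
                    utils::adist(revcomp(seqs[i]), seqs[c])) / L
      if (id >= thr) { hit <- c; break }
    }
    if (hit) assign[i] <- hit else { cent <- c(cent, i); assign[i] <- i }
  }
  assign
}

# brute-force digest oracle: scan every position for either motif
# (overlap-safe), enumerate adjacent heterologous inter-cut intervals
oracle_digest <- function(genome, site1 = "TTAATTAA", site2 = "ATGCAT",
                          size_min = 150) {
  L <- nchar(genome)
  pos <- seq_len(L)
  hit1 <- pos[substring(genome, pos, pos + nchar(site1) - 1) == site1]
  hit2 <- pos[substring(genome, pos, pos + nchar(site2) - 1) == site2]
  cut <- c(hit1 - 1 + nchar(site1) %/% 2, hit2 - 1 + nchar(site2) %/% 2)
  enz <- rep(c("site1", "site2"), c(length(hit1), length(hit2)))
  o <- order(cut)
  cut <- cut[o]; enz <- enz[o]
  out <- NULL
  for (i in seq_len(max(0, length(cut) - 1))) {
    len <- cut[i + 1] - cut[i]
    if (enz[i] != enz[i + 1] && len >= size_min)
      out <- rbind(out, data.frame(start = cut[i], end = cut[i + 1]))
  }
  out
}

# dereplication oracle: independent counting via sort + rle
oracle_dereplicate <- function(seqs, min_unique_size) {
  r <- rle(sort(seqs))
  keep <- r$lengths >= min_unique_size
  data.frame(sequence = r$values[keep], abundance = r$lengths[keep])
}

# random monoculture count matrix with a planted cross-contamination
# structure: strong own-species counts, weak-to-moderate leakage into the
# other monocultures -- so all three filter outcomes occur
random_mono_counts <- function(k, nc) {
  species <- paste0("sp", seq_len(k))
  mono <- paste0("mono_", species)
  own <- sample(species, nc, replace = TRUE)
  m <- matrix(rpois(nc * k, 1.5), nc, k,
              dimnames = list(paste0(own, "_", seq_len(nc)), mono))
  for (i in seq_len(nc)) {
    m[i, match(own[i], species)] <- rpois(1, sample(c(4, 12, 60, 400), 1))
    if (runif(1) < 0.4)  # occasional heavy leakage
      m[i, sample(k, 1)] <- m[i, sample(k, 1)] + rpois(1, 30)
  }
  storage.mode(m) <- "integer"
  make_counts(m, setNames(own, rownames(m)),
              setNames(rep("monoculture", k), mono),
              setNames(species, mono))
}

# annotated count matrix built directly (for worked examples)
make_counts <- function(m, cluster_species, sample_roles,
                        mono_species = NULL) {
  if (is.null(mono_species)) {
    mono <- names(sample_roles)[sample_roles == "monoculture"]
    mono_species <- setNames(sub("^mono_", "", mono), mono)
  }
  structure(m, cluster_species = cluster_species[rownames(m)],
            sample_roles = sample_roles,
            mono_species = mono_species,
            class = c("msgbs_counts", class(m)))
}
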