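#' Simulate species genomes with controllable cross-species homology
#'
#' Generates random genomes for `n_species` species and, where requested,
#' copies segments verbatim between genome pairs so that a controllable
#' fraction of each recipient genome is shared with a donor species.
#' Shared segments are the raw material for cross-species homologous GBS
#' clusters, the case the monoculture-based cluster filter exists to
#' remove. Restriction sites for both enzymes are seeded explicitly at
#' roughly `site_spacing` intervals (on top of chance occurrences) so every
#' genome yields a usable set of heterologous-ended fragments.
#'
#' @param n_species number of species (>= 1).
#' @param genome_length genome length in bp (>= 10000).
#' @param homology either a single fraction applied to every consecutive
#'   species pair (1-2, 3-4, ...), an `n_species` x `n_species` matrix of
#'   pairwise shared fractions (upper triangle used, row = donor), or a
#'   data.frame with columns `donor`, `recipient`, `fraction`. Fractions
#'   are of the recipient genome length; segments are copied verbatim.
#' @param segment_length length in bp of each copied homologous segment
#'   (at least 300).
#' @param site1,site2 recognition motifs seeded into the genomes; defaults
#'   are the canonical PacI (TTAATTAA) and NsiI (ATGCAT) sites.
#' @param site_spacing mean spacing of explicitly seeded sites per enzyme.
#' @param seed integer RNG seed (mandatory; generation is deterministic
#'   given the seed).
#' @return an object of class `msgbs_genomes`: a named character vector of
#'   genome sequences (names are species ids `sp1`, `sp2`, ...) with a
#'   `homology` attribute recording the realized donor/recipient segments.
#' @examples
#' g <- simulate_genomes(2, 5e4, homology = 0.1, seed = 1)
#' nchar(g)
#' @export
simulate_genomes <- function(n_species, genome_length,
                             homology = 0, segment_length = 2000,
                             site1 = "TTAATTAA", site2 = "ATGCAT",
                             site_spacing = 1500, seed) {
  stopifnot(n_species >= 1, genome_length >= 10000)
  pairs <- homology_pairs(homology, n_species)
  if (nrow(pairs) && any(pairs$fraction > 1 | pairs$fraction < 0))
    stop("homology fractions must lie in [0, 1]", call. = FALSE)
  if (segment_length < 300) stop("segment_length must be >= 300", call. = FALSE)
  with_seed(seed, {
    genomes <- random_dna(n_species, genome_length)
    names(genomes) <- paste0("sp", seq_len(n_species))
    # seed restriction sites so digestion always yields fragments
    n_sites <- max(1L, round(genome_length / site_spacing))
    for (i in seq_len(n_species)) {
      for (motif in c(site1, site2)) {
        pos <- sample.int(genome_length - nchar(motif), n_sites)
        for (p in pos) substr(genomes[i], p, p + nchar(motif) - 1L) <- motif
      }
    }
    seg_log <- NULL
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        d <- pairs$donor[r]; rec <- pairs$recipient[r]
        f <- pairs$fraction[r]
        if (f <= 0) next
        n_seg <- max(1L, round(f * genome_length / segment_length))
        don_pos <- sample.int(genome_length - segment_length, n_seg)
        rec_pos <- sample.int(genome_length - segment_length, n_seg)
        for (s in seq_len(n_seg)) {
          seg <- substr(genomes[d], don_pos[s], don_pos[s] + segment_length - 1L)
          substr(genomes[rec], rec_pos[s],
                 rec_pos[s] + segment_length - 1L) <- seg
        }
        seg_log <- rbind(seg_log, data.frame(
          donor = names(genomes)[d], recipient = names(genomes)[rec],
          n_segments = n_seg, segment_length = segment_length,
          fraction = f))
      }
    }
    structure(genomes, homology = seg_log, class = "msgbs_genomes")
  })
}

# Normalize the homology argument to a (donor, recipient, fraction) table.
#' @noRd
homology_pairs <- function(homology, n_species) {
  if (is.data.frame(homology)) {
    stopifnot(all(c("donor", "recipient", "fraction") %in% names(homology)))
    return(homology)
  }
  if (is.matrix(homology)) {
    idx <- which(upper.tri(homology) & homology > 0, arr.ind = TRUE)
    return(data.frame(donor = idx[, 1], recipient = idx[, 2],
                      fraction = homology[idx]))
  }
  stopifnot(is.numeric(homology), length(homology) == 1)
  if (homology == 0 || n_species < 2)
    return(data.frame(donor = integer(), recipient = integer(),
                      fraction = numeric()))
  d <- seq(1, n_species - 1, by = 2)
  data.frame(donor = d, recipient = d + 1, fraction = homology)
}

#' In silico double restriction digest
#'
#' Cuts a genome at every occurrence of two recognition motifs (cut point
#' at the motif midpoint) and returns the inter-cut fragments. Under the
#' two-adapter GBS chemistry only fragments with one end cut by each
#' enzyme amplify, so homologous-ended fragments are discarded by default,
#' as are fragments shorter than the size-selection minimum.
#'
#' @param genome a single DNA string (or one element of
#'   [simulate_genomes()] output).
#' @param site1,site2 recognition motifs of the two enzymes.
#' @param size_min minimum retained fragment length (bp); size selection
#'   is modelled as this hard lower bound.
#' @param hetero_only if `TRUE` (default) keep only fragments whose two
#'   ends were cut by different enzymes.
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   coordinates on the forward strand), `enzyme5`, `enzyme3`, `length`
#'   and `seq`. A genome without cut sites yields zero rows.
#' @export
digest_genome <- function(genome, site1 = "TTAATTAA", site2 = "ATGCAT",
                          size_min = 150, hetero_only = TRUE) {
  stopifnot(nzchar(site1), nzchar(site2))
  genome <- as.character(genome)
  cuts1 <- site_positions(genome, site1)
  cuts2 <- site_positions(genome, site2)
  cut <- c(cuts1 + nchar(site1) %/% 2, cuts2 + nchar(site2) %/% 2)
  enz <- rep(c("site1", "site2"), c(length(cuts1), length(cuts2)))
  if (length(cut) < 2)
    return(data.frame(start = integer(), end = integer(),
                      enzyme5 = character(), enzyme3 = character(),
                      length = integer(), seq = character()))
  o <- order(cut)
  cut <- cut[o]; enz <- enz[o]
  n <- length(cut) - 1L
  fr <- data.frame(start = cut[seq_len(n)], end = cut[-1L],
                   enzyme5 = enz[seq_len(n)], enzyme3 = enz[-1L])
  fr$length <- fr$end - fr$start
  keep <- fr$length >= size_min
  if (hetero_only) keep <- keep & (fr$enzyme5 != fr$enzyme3)
  fr <- fr[keep, , drop = FALSE]
  fr$seq <- if (nrow(fr)) substring(genome, fr$start + 1L, fr$end)
            else character(0)
  rownames(fr) <- NULL
  fr
}

# 0-based start positions of all (possibly overlapping) motif occurrences.
# Candidate anchoring on the first motif base keeps this linear and
# overlap-safe, unlike gregexpr which skips overlapping matches.
#' @noRd
site_positions <- function(genome, motif) {
  first <- charToRaw(substr(motif, 1, 1))
  cand <- which(charToRaw(genome) == first)
  cand <- cand[cand + nchar(motif) - 1L <= nchar(genome)]
  if (!length(cand)) return(integer(0))
  hits <- cand[substring(genome, cand, cand + nchar(motif) - 1L) == motif]
  hits - 1L  # 0-based
}

#' Specify one sample of a GBS library
#'
#' @param sample_id sample label.
#' @param role one of `"monoculture"`, `"calibration"`, `"mixture"`.
#'   Monocultures must have exactly one species at proportion 1;
#'   calibration samples must have equal proportions across their species.
#' @param proportions named numeric vector of biomass fractions per
#'   species id; must sum to 1.
#' @param n_fragments number of sequenced fragments (before PCR
#'   duplication) for this sample.
#' @param index_pair optional character(2) of adapter index tags; assigned
#'   automatically by [library_design()] when omitted.
#' @return a `sample_spec` list.
#' @export
sample_spec <- function(sample_id, role, proportions, n_fragments,
                        index_pair = NULL) {
  role <- match.arg(role, c("monoculture", "calibration", "mixture"))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1 for sample ", sample_id, call. = FALSE)
  if (any(proportions < 0))
    stop("proportions must be >= 0", call. = FALSE)
  if (role == "monoculture" && sum(proportions > 0) != 1L)
    stop("a monoculture sample must contain exactly one species",
         call. = FALSE)
  if (role == "calibration") {
    nz <- proportions[proportions > 0]
    if (max(nz) - min(nz) > 1e-8)
      stop("a calibration sample must have equal per-species proportions",
           call. = FALSE)
  }
  structure(list(sample_id = sample_id, role = role,
                 proportions = proportions,
                 n_fragments = as.integer(n_fragments),
                 index_pair = index_pair),
            class = "sample_spec")
}

#' Generate mutually distinguishable adapter index tags
#'
#' @param n number of tags.
#' @param length tag length in nt (default 5).
#' @param min_dist minimum pairwise Hamming distance (default 3, enough
#'   for unambiguous 1-mismatch demultiplexing).
#' @return character vector of `n` tags.
#' @export
make_index_tags <- function(n, length = 5, min_dist = 3) {
  tags <- character(0)
  tries <- 0L
  while (length(tags) < n) {
    cand <- random_dna(1, length)
    if (!length(tags) ||
        all(vapply(tags, function(t) hamming_dist(t, cand),
                   integer(1)) >= min_dist))
      tags <- c(tags, cand)
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("cannot find ", n, " tags of length ", length,
           " at distance ", min_dist, call. = FALSE)
  }
  tags
}

#' @noRd
hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Describe a simulated GBS library
#'
#' Collects the per-sample specifications and library-wide parameters of a
#' simulated sequencing run. `yield_factor` models the biomass-independent
#' species-specific variation in reads per unit biomass (gDNA yield,
#' fragment recovery); `locus_weight_sdlog` models per-locus coverage bias
#' (PCR/size bias), drawn once per (species, fragment) for the whole
#' library so monoculture, calibration and mixture samples see the same
#' bias, as aliquots of one pooled library would.
#'
#' @param samples list of [sample_spec()] objects.
#' @param duplication_rate expected fraction of emitted read pairs that
#'   are PCR re-emissions of an earlier molecule (same fragment and UMI
#'   pair). Default 0.2.
#' @param error_rate per-base substitution probability (default 0.001).
#' @param yield_factor named positive multiplier per species (default 1).
#' @param seed integer RNG seed, mandatory.
#' @param read_length sequenced insert length per mate after the UMI and
#'   index prefix (default 150 nt).
#' @param umi_length UMI nucleotides per mate (default 3).
#' @param index_length adapter index length (default 5 nt).
#' @param locus_weight_sdlog sdlog of the lognormal per-locus weights
#'   (default 1.5; 0 disables coverage bias).
#' @param short_bias_bp length scale of the exponential amplification
#'   preference for short fragments (weight multiplier
#'   `exp(-length / short_bias_bp)`; default 800 bp, `Inf` disables).
#'   Together with the lognormal weights this reproduces the strongly
#'   uneven per-locus coverage of real GBS libraries, where many loci sit
#'   near the dereplication detection limit.
#' @param monoculture_impurity fraction of a monoculture sample's
#'   molecules drawn from the other species (default 0.02). Field-grown
#'   monoculture root material is never perfectly pure; this trace
#'   cross-contamination is what seeds mislabelled reference clusters and
#'   non-target monoculture read counts, the signal the monoculture-based
#'   cluster filter is designed to detect. Set 0 for ideal monocultures.
#' @param phix_rate,dimer_rate fractions of the final read stream that are
#'   unassignable contamination (random-genome reads, adapter dimers);
#'   default 0.
#' @param base_quality constant phred quality of simulated bases.
#' @param adapter adapter sequence used for 3' read-through when a
#'   fragment is shorter than `read_length`.
#' @return a `library_design` list.
#' @export
library_design <- function(samples, duplication_rate = 0.2,
                           error_rate = 0.001, yield_factor = NULL,
                           seed, read_length = 150, umi_length = 3,
                           index_length = 5, locus_weight_sdlog = 1.5,
                           short_bias_bp = 800, monoculture_impurity = 0.02,
                           phix_rate = 0, dimer_rate = 0,
                           base_quality = 30,
                           adapter = "AGATCGGAAGAGCACACGTCT") {
  stopifnot(duplication_rate >= 0, duplication_rate < 1,
            error_rate >= 0, error_rate <= 1,
            phix_rate >= 0, phix_rate < 1, dimer_rate >= 0, dimer_rate < 1)
  if (!length(samples)) stop("at least one sample is required", call. = FALSE)
  if (!is.null(yield_factor) && any(yield_factor <= 0))
    stop("yield factors must be > 0", call. = FALSE)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  # assign index pairs where missing: combinatorial dual indexing from a
  # small tag set, as real dual-indexed GBS libraries do
  need <- vapply(samples, function(s) is.null(s$index_pair), logical(1))
  if (any(need)) {
    k <- ceiling(sqrt(sum(need)))
    tags <- with_seed(seed + 7777L,
                      make_index_tags(2L * k, index_length))
    t1 <- tags[seq_len(k)]
    t2 <- tags[k + seq_len(k)]
    grid <- expand.grid(i1 = t1, i2 = t2, stringsAsFactors = FALSE)
    j <- 0L
    for (i in which(need)) {
      j <- j + 1L
      samples[[i]]$index_pair <- c(grid$i1[j], grid$i2[j])
    }
  }
  structure(list(samples = samples, duplication_rate = duplication_rate,
                 error_rate = error_rate, yield_factor = yield_factor,
                 seed = as.integer(seed), read_length = read_length,
                 umi_length = umi_length, index_length = index_length,
                 locus_weight_sdlog = locus_weight_sdlog,
                 short_bias_bp = short_bias_bp,
                 monoculture_impurity = monoculture_impurity,
                 phix_rate = phix_rate, dimer_rate = dimer_rate,
                 base_quality = base_quality, adapter = adapter),
            class = "library_design")
}

#' Sample sheet of a library design
#'
#' @param design a [library_design()].
#' @return data.frame with columns `sample_id`, `role`, `index1`,
#'   `index2`, `species_id` (the species for monocultures, `NA`
#'   otherwise).
#' @export
sample_sheet <- function(design) {
  stopifnot(inherits(design, "library_design"))
  do.call(rbind, lapply(design$samples, function(s) {
    data.frame(sample_id = s$sample_id, role = s$role,
               index1 = s$index_pair[1], index2 = s$index_pair[2],
               species_id = if (s$role == "monoculture")
                 names(s$proportions)[s$proportions > 0] else NA_character_)
  }))
}

#' Simulate a paired-end GBS sequencing library
#'
#' Digests every genome, then for each sample draws sequenced molecules:
#' species according to biomass proportion x yield factor, fragment within
#' species according to the library's per-locus weights. Each molecule
#' receives an independent random UMI on each mate; PCR duplicates are
#' re-emissions of earlier molecules (same fragment, same UMI pair) at the
#' design's duplication rate; substitution errors are applied to every
#' base of the final reads (UMI and index included). Mate 1 reads the 5'
#' fragment end, mate 2 the reverse complement of the 3' end, each
#' `read_length` insert nt after the 3-nt UMI and the index tag.
#'
#' @param genomes a [simulate_genomes()] result (or named character vector
#'   of genome sequences).
#' @param design a [library_design()].
#' @param site1,site2,size_min digestion parameters, see [digest_genome()].
#' @return an object of class `msgbs_library`: list with `reads1`,
#'   `reads2`, `qual1`, `qual2` (parallel character vectors over all
#'   emitted pairs), `sheet` (the sample sheet), `truth` (list of
#'   `pairs` — one row per emitted read pair with sample, species,
#'   fragment, UMIs and duplicate flag — `counts` — per sample x species
#'   fresh-molecule counts and true proportions — and `fragments` — the
#'   per-species digested fragment tables), and `design`.
#' @export
simulate_library <- function(genomes, design, site1 = "TTAATTAA",
                             site2 = "ATGCAT", size_min = 150) {
  stopifnot(inherits(design, "library_design"))
  species_all <- names(genomes)
  for (s in design$samples) {
    missing <- setdiff(names(s$proportions)[s$proportions > 0], species_all)
    if (length(missing))
      stop("sample ", s$sample_id, " requests species without a genome: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  frags <- lapply(species_all, function(sp)
    digest_genome(genomes[[sp]], site1, site2, size_min))
  names(frags) <- species_all
  yf <- setNames(rep(1, length(species_all)), species_all)
  if (!is.null(design$yield_factor))
    yf[names(design$yield_factor)] <- design$yield_factor

  with_seed(design$seed, {
    # library-wide per-locus weights (same aliquot bias in every sample)
    weights <- lapply(species_all, function(sp) {
      n <- nrow(frags[[sp]])
      if (!n) return(numeric(0))
      w <- if (design$locus_weight_sdlog > 0)
        rlnorm(n, 0, design$locus_weight_sdlog) else rep(1, n)
      if (is.finite(design$short_bias_bp))
        w <- w * exp(-frags[[sp]]$length / design$short_bias_bp)
      w
    })
    names(weights) <- species_all

    per_sample <- lapply(design$samples, function(s)
      simulate_sample_reads(s, frags, weights, yf, design))
    pairs <- do.call(rbind, lapply(per_sample, `[[`, "pairs"))
    counts <- do.call(rbind, lapply(per_sample, `[[`, "counts"))
    reads <- build_read_strings(pairs, frags, design)

    # unassignable contamination
    n_real <- nrow(pairs)
    contam_rate <- design$phix_rate + design$dimer_rate
    if (contam_rate > 0) {
      n_contam <- round(n_real * contam_rate / (1 - contam_rate))
      n_phix <- round(n_contam * design$phix_rate / contam_rate)
      creads <- simulate_contamination(n_phix, n_contam - n_phix, design)
      reads$r1 <- c(reads$r1, creads$r1)
      reads$r2 <- c(reads$r2, creads$r2)
      pairs <- rbind(pairs, data.frame(
        sample_id = NA_character_, species_id = NA_character_,
        fragment = NA_integer_, umi1 = NA_character_,
        umi2 = NA_character_, is_duplicate = FALSE,
        origin = creads$origin))
    }
    if (design$error_rate > 0) {
      reads$r1 <- cpp_add_errors(reads$r1, design$error_rate)
      reads$r2 <- cpp_add_errors(reads$r2, design$error_rate)
    }
    qchar <- rawToChar(as.raw(33L + design$base_quality))
    qual <- strrep(qchar, nchar(reads$r1))
    qual2 <- strrep(qchar, nchar(reads$r2))
    structure(list(reads1 = reads$r1, reads2 = reads$r2,
                   qual1 = qual, qual2 = qual2,
                   sheet = sample_sheet(design),
                   truth = list(pairs = pairs, counts = counts,
                                fragments = frags),
                   design = design),
              class = "msgbs_library")
  })
}

# Draw the molecule table for one sample: fresh molecules then duplicates.
#' @noRd
simulate_sample_reads <- function(s, frags, weights, yf, design) {
  prop <- s$proportions
  imp <- design$monoculture_impurity %||% 0
  if (s$role == "monoculture" && imp > 0 && length(frags) > 1) {
    # trace cross-contamination of field monoculture material
    others <- setdiff(names(frags), names(prop)[prop > 0])
    prop <- c(prop[prop > 0] * (1 - imp),
              setNames(rep(imp / length(others), length(others)), others))
  }
  sp <- names(prop)[prop > 0]
  empty <- sp[vapply(sp, function(x) nrow(frags[[x]]) == 0, logical(1))]
  if (length(empty))
    stop("no digestible fragments for species: ",
         paste(empty, collapse = ", "), call. = FALSE)
  p <- prop[sp] * yf[sp]
  p <- p / sum(p)
  n <- s$n_fragments
  n_sp <- as.vector(rmultinom(1, n, p))
  species <- rep(sp, n_sp)
  fragment <- unlist(lapply(seq_along(sp), function(i) {
    if (n_sp[i] == 0) return(integer(0))
    w <- weights[[sp[i]]]
    sample.int(length(w), n_sp[i], replace = TRUE, prob = w)
  }), use.names = FALSE)
  o <- sample.int(n)  # shuffle molecules
  species <- species[o]; fragment <- fragment[o]
  umi1 <- random_tags(n, design$umi_length)
  umi2 <- random_tags(n, design$umi_length)
  fresh <- data.frame(sample_id = s$sample_id, species_id = species,
                      fragment = fragment, umi1 = umi1, umi2 = umi2,
                      is_duplicate = FALSE, origin = "sample")
  d <- design$duplication_rate
  if (d > 0) {
    total <- round(n / (1 - d))
    ndup <- total - n
    src <- sample.int(n, ndup, replace = TRUE)
    dup <- fresh[src, , drop = FALSE]
    dup$is_duplicate <- TRUE
    fresh <- rbind(fresh, dup)
  }
  cnt <- as.data.frame(table(species_id = species), stringsAsFactors = FALSE)
  names(cnt)[2] <- "true_fragments"
  cnt$sample_id <- s$sample_id
  cnt$true_proportion <- as.vector(s$proportions[cnt$species_id])
  cnt$true_proportion[is.na(cnt$true_proportion)] <- 0
  list(pairs = fresh, counts = cnt[, c("sample_id", "species_id",
                                       "true_fragments", "true_proportion")])
}

# Fast batch generation of short random tags.
#' @noRd
random_tags <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m))
}

# Assemble the full mate sequences (UMI + index + insert [+ adapter
# read-through]) for a molecule table.
#' @noRd
build_read_strings <- function(pairs, frags, design) {
  sheet <- sample_sheet(design)
  idx1 <- sheet$index1[match(pairs$sample_id, sheet$sample_id)]
  idx2 <- sheet$index2[match(pairs$sample_id, sheet$sample_id)]
  frag_seq <- character(nrow(pairs))
  for (sp in unique(pairs$species_id)) {
    i <- which(pairs$species_id == sp)
    frag_seq[i] <- frags[[sp]]$seq[pairs$fragment[i]]
  }
  rl <- design$read_length
  ins1 <- substr(frag_seq, 1L, rl)
  ins2 <- substr(revcomp(frag_seq), 1L, rl)
  short <- nchar(frag_seq) < rl
  if (any(short)) {
    pad <- rl - nchar(frag_seq[short])
    fill <- substr(strrep(design$adapter,
                          ceiling(max(pad) / nchar(design$adapter)) + 1L),
                   1L, max(pad))
    ins1[short] <- paste0(ins1[short], substr(fill, 1L, pad))
    ins2[short] <- paste0(ins2[short], substr(fill, 1L, pad))
  }
  list(r1 = paste0(pairs$umi1, idx1, ins1),
       r2 = paste0(pairs$umi2, idx2, ins2))
}

#' @noRd
simulate_contamination <- function(n_phix, n_dimer, design) {
  rl <- design$read_length + design$umi_length + design$index_length
  r1 <- character(0); r2 <- character(0); origin <- character(0)
  if (n_phix > 0) {
    g <- random_dna(1, 6000)
    pos <- sample.int(6000 - 400, n_phix, replace = TRUE)
    fr <- substring(g, pos, pos + 399)
    r1 <- c(r1, paste0(random_tags(n_phix, design$umi_length),
                       substr(fr, 1, rl - design$umi_length)))
    r2 <- c(r2, paste0(random_tags(n_phix, design$umi_length),
                       substr(revcomp(fr), 1, rl - design$umi_length)))
    origin <- c(origin, rep("phix", n_phix))
  }
  if (n_dimer > 0) {
    core <- strrep(design$adapter, 3L)
    r1 <- c(r1, paste0(random_tags(n_dimer, design$umi_length),
                       random_tags(n_dimer, design$index_length),
                       substr(core, 1, design$read_length)))
    r2 <- c(r2, paste0(random_tags(n_dimer, design$umi_length),
                       random_tags(n_dimer, design$index_length),
                       substr(core, 1, design$read_length)))
    origin <- c(origin, rep("dimer", n_dimer))
  }
  list(r1 = r1, r2 = r2, origin = origin)
}

#' Rotating mock-mixture design
#'
#' Builds a grid of mixture proportion vectors in which each species in
#' turn anchors the mixture at 50% biomass and the remaining species
#' receive a seeded permutation of the remaining proportions (including
#' zeros, so every species is also absent from some mixtures). Mirrors a
#' mock-community design spanning 0-50% per-species biomass.
#'
#' @param species character vector of species ids.
#' @param n_per_anchor mixtures per anchoring species (default 5).
#' @param base proportions distributed over the non-anchor species;
#'   must have length `length(species) - 1` and sum to 0.5.
#' @param seed RNG seed for the permutations.
#' @return matrix (mixtures x species) of true biomass proportions.
#' @export
mixture_design_grid <- function(species,
                                n_per_anchor = 5,
                                base = NULL, seed = 1) {
  k <- length(species)
  if (is.null(base)) {
    base <- if (k >= 6) c(0.2, 0.1, 0.1, 0.05, 0.05, rep(0, k - 6))
            else if (k > 2) c(rep(0.5 / (k - 2), k - 2), 0)
            else 0.5
  }
  stopifnot(length(base) == k - 1, abs(sum(base) - 0.5) < 1e-8)
  with_seed(seed, {
    rows <- list()
    for (anchor in seq_len(k)) {
      for (r in seq_len(n_per_anchor)) {
        v <- numeric(k)
        v[anchor] <- 0.5
        v[-anchor] <- sample(base)
        rows[[length(rows) + 1L]] <- v
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- species
    rownames(m) <- sprintf("mix%02d", seq_len(nrow(m)))
    m
  })
}

#' Simulate a complete msGBS study
#'
#' One-call generator of a full synthetic study: genomes, monoculture
#' samples (one per species), equal-proportion calibration samples, and a
#' grid of mock mixtures with known biomass proportions, sequenced into a
#' paired-end read set with UMIs, PCR duplicates and substitution errors.
#'
#' @param n_species number of species (default 8, one species pool).
#' @param genome_length genome length in bp (default 1e6).
#' @param homology pairwise shared-genome fraction passed to
#'   [simulate_genomes()] (default 0).
#' @param yield_factors named or unnamed positive multipliers per species;
#'   the default spans a 20-fold range across species, the magnitude of
#'   between-species variation in reads per unit biomass that makes
#'   calibration necessary.
#' @param n_calibration number of calibration samples (default 6).
#' @param mixtures matrix of true mixture proportions (mixtures x
#'   species); default [mixture_design_grid()] over all species.
#' @param depth_monoculture,depth_calibration,depth_mixture sequenced
#'   fragments per sample of each role.
#' @param duplication_rate,error_rate library parameters, see
#'   [library_design()].
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param ... further arguments passed to [library_design()].
#' @return list with `genomes`, `design`, `library` (an `msgbs_library`),
#'   `sheet`, and `mixtures` (the truth matrix).
#' @export
simulate_msgbs_dataset <- function(n_species = 8, genome_length = 1e6,
                                   homology = 0, yield_factors = NULL,
                                   n_calibration = 6, mixtures = NULL,
                                   depth_monoculture = 20000,
                                   depth_calibration = 20000,
                                   depth_mixture = 20000,
                                   duplication_rate = 0.2,
                                   error_rate = 0.001, seed, ...) {
  genomes <- simulate_genomes(n_species, genome_length, homology = homology,
                              seed = seed)
  species <- names(genomes)
  if (is.null(yield_factors)) {
    yield_factors <- exp(seq(log(0.3), log(6), length.out = n_species))
  }
  if (is.null(names(yield_factors))) names(yield_factors) <- species
  samples <- list()
  for (sp in species) {
    p <- setNames(as.numeric(species == sp), species)
    samples[[length(samples) + 1L]] <-
      sample_spec(paste0("mono_", sp), "monoculture", p[p > 0],
                  depth_monoculture)
  }
  for (i in seq_len(n_calibration)) {
    p <- setNames(rep(1 / n_species, n_species), species)
    samples[[length(samples) + 1L]] <-
      sample_spec(sprintf("cal%02d", i), "calibration", p, depth_calibration)
  }
  if (is.null(mixtures))
    mixtures <- mixture_design_grid(species, seed = seed + 101L)
  for (i in seq_len(nrow(mixtures))) {
    p <- mixtures[i, ]
    samples[[length(samples) + 1L]] <-
      sample_spec(rownames(mixtures)[i], "mixture", p[p > 0], depth_mixture)
  }
  design <- library_design(samples, duplication_rate = duplication_rate,
                           error_rate = error_rate,
                           yield_factor = yield_factors,
                           seed = seed + 202L, ...)
  lib <- simulate_library(genomes, design)
  list(genomes = genomes, design = design, library = lib,
       sheet = lib$sheet, mixtures = mixtures)
}
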