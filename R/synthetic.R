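random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic promoter model
#'
#' Builds a synthetic subfamily promoter model for simulation and testing:
#' monomers are substitution-diverged copies of one random ancestral
#' monomer (tandem monomers in real 5'UTRs are paralogous, with
#' monomer-to-monomer identities of roughly 75-97%), and the tether is an
#' unrelated random sequence. This stands in for a real consensus model;
#' it reproduces the tandem-repeat structure, not any real subfamily's
#' sequence.
#'
#' @param monomer_lengths monomer lengths 5' to 3' (default `c(212, 212,
#'   197)`, a three-monomer model whose duplicated unit is 212 bp).
#' @param tether_length tether length in bp (default 205).
#' @param divergence per-base substitution probability between the
#'   ancestral monomer and each model monomer (default 0.1).
#' @param subfamily,pattern_id labels for the model.
#' @param seed RNG seed.
#' @return a [promoter_model()].
#' @export
random_promoter_model <- function(monomer_lengths = c(212L, 212L, 197L),
                                  tether_length = 205L, divergence = 0.1,
                                  subfamily = "SimA", pattern_id = "default",
                                  seed = 1L) {
  set.seed(seed)
  base <- random_dna(max(monomer_lengths))
  monomers <- vapply(monomer_lengths, function(L) {
    mutate_sequence(substr(base, 1L, L), substitution_rate = divergence)
  }, character(1))
  promoter_model(
    subfamily = subfamily,
    monomers = monomers,
    tether = random_dna(tether_length),
    pattern_id = pattern_id,
    notes = "synthetic model (random ancestral monomer + diverged copies)"
  )
}

#' Configuration for locus simulation
#'
#' Describes the population of simulated L1 loci: how many monomers each
#' locus retains, where inside the outermost monomer the 5'-truncation
#' point falls (a uniform background mixed with single-nucleotide
#' hotspots; the default hotspots at offsets 83 and 86 with weights 0.166
#' and 0.263 echo the dominant truncation peaks of young subfamilies),
#' per-base substitution and indel rates, and the fractions of
#' 3'-tether-truncated and decoy (random-composition) loci.
#'
#' @param model a [promoter_model()].
#' @param n number of loci (>= 1).
#' @param count_probs probability of a locus starting in monomer slot
#'   `i = 1 ... total_monomers` (categorical; must sum to 1). The default
#'   peaks at the third monomer, as in young subfamilies.
#' @param hotspots data frame with columns `offset`, `weight`: point-mass
#'   truncation positions within the outermost monomer; weights must sum
#'   to < 1, the remainder is uniform over the monomer.
#' @param substitution_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel probability in `[0, 1)`.
#' @param indel_geom_p geometric length parameter for indels.
#' @param frac_tether_truncated fraction of loci missing >= 11 bp from the
#'   tether 3' end (these must fail the tether-tail filter).
#' @param frac_decoy fraction of random-composition decoy loci with the
#'   same length distribution.
#' @param total_monomers query/locus monomer capacity (default 11).
#' @return an object of class `locus_sim_config`.
#' @export
locus_sim_config <- function(model, n = 500L,
                             count_probs = c(0.07, 0.25, 0.32, 0.18, 0.09,
                               0.05, 0.02, 0.01, 0.005, 0.004, 0.001),
                             hotspots = data.frame(
                               offset = c(83L, 86L), weight = c(0.166, 0.263)
                             ),
                             substitution_rate = 0.01, indel_rate = 0,
                             indel_geom_p = 0.5,
                             frac_tether_truncated = 0.05,
                             frac_decoy = 0.05,
                             total_monomers = 11L) {
  stopifnot(inherits(model, "promoter_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("invalid config: n must be >= 1")
  if (length(count_probs) != total_monomers || any(count_probs < 0) ||
    abs(sum(count_probs) - 1) > 1e-8) {
    stop("invalid config: count_probs must be a probability vector over 1..total_monomers")
  }
  if (any(hotspots$weight < 0) || sum(hotspots$weight) >= 1) {
    stop("invalid config: hotspot weights must be >= 0 and sum to < 1")
  }
  for (r in c(substitution_rate, indel_rate)) {
    if (r < 0 || r >= 1) stop("invalid config: rates must be in [0, 1)")
  }
  if (frac_tether_truncated < 0 || frac_decoy < 0 ||
    frac_tether_truncated + frac_decoy > 1) {
    stop("invalid config: class fractions must be probabilities summing to <= 1")
  }
  structure(
    list(
      model = model, n = n, count_probs = count_probs, hotspots = hotspots,
      substitution_rate = substitution_rate, indel_rate = indel_rate,
      indel_geom_p = indel_geom_p,
      frac_tether_truncated = frac_tether_truncated,
      frac_decoy = frac_decoy, total_monomers = as.integer(total_monomers)
    ),
    class = "locus_sim_config"
  )
}

#' Mutate a DNA sequence
#'
#' Applies per-base substitutions (a substituted base always changes) and
#' geometric-length insertions/deletions. Reproducible for a given seed;
#' with `seed = NULL` the current RNG stream is used, so callers drawing
#' many sequences stay reproducible from one upstream seed.
#'
#' @param seq uppercase DNA string.
#' @param substitution_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel probability in `[0, 1)`.
#' @param indel_geom_p geometric parameter for indel lengths (length is
#'   `1 + rgeom(indel_geom_p)`).
#' @param seed optional RNG seed.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate = 0,
                            indel_geom_p = 0.5, seed = NULL) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
    indel_rate < 0 || indel_rate >= 1) {
    stop("invalid config: rates must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (substitution_rate > 0) {
    hit <- which(stats::runif(n) < substitution_rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    }
  }
  if (indel_rate > 0) {
    sites <- which(stats::runif(n) < indel_rate)
    # apply right-to-left so earlier positions stay valid
    for (i in rev(sites)) {
      len <- 1L + stats::rgeom(1L, indel_geom_p)
      if (stats::runif(1) < 0.5) { # deletion
        chars <- chars[-(i:min(i + len - 1L, length(chars)))]
      } else { # insertion after position i
        ins <- sample(bases, len, replace = TRUE)
        chars <- append(chars, ins, after = i)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate L1 loci with known truncation truth
#'
#' Each clean locus is a 5'-truncated copy of the extended promoter
#' sequence (truncation point drawn from the configured monomer-count and
#' offset distributions) running through the full tether, then mutated at
#' the configured rates. Tether-truncated loci additionally lose at least
#' 11 bp from the tether 3' end, which guarantees rejection by the
#' default 10-bp tether-tail filter. Decoy loci are random-composition
#' sequences with the same length distribution and share no construction
#' with the model. Fully reproducible given the seed.
#'
#' @param cfg a [locus_sim_config()].
#' @param seed RNG seed (default 1).
#' @return list with `sequences` (named character vector, FASTA-ready),
#'   `truth` (data frame `locus_id`, `class`, `bin`, `offset`,
#'   `monomer_count`), `query` (the extended query used), and `seed`.
#' @export
simulate_loci <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "locus_sim_config"))
  set.seed(seed)
  query <- build_extended_query(cfg$model, cfg$total_monomers)
  classes <- sample(
    c("clean", "tether_truncated", "decoy"), cfg$n,
    replace = TRUE,
    prob = c(
      1 - cfg$frac_tether_truncated - cfg$frac_decoy,
      cfg$frac_tether_truncated, cfg$frac_decoy
    )
  )
  lq <- nchar(query$sequence)
  tether_len <- nchar(cfg$model$tether)
  seqs <- character(cfg$n)
  truth <- vector("list", cfg$n)
  for (i in seq_len(cfg$n)) {
    id <- sprintf("locus_%04d", i)
    slot <- sample.int(cfg$total_monomers, 1L, prob = cfg$count_probs)
    label <- paste0("M", slot)
    dom_len <- query$domains$length[query$domains$label == label]
    usable <- cfg$hotspots$offset <= dom_len
    w <- cfg$hotspots$weight[usable]
    u <- stats::runif(1)
    offset <- if (length(w) > 0L && u < sum(w)) {
      cfg$hotspots$offset[usable][findInterval(u, cumsum(w)) + 1L]
    } else {
      sample.int(dom_len, 1L)
    }
    p <- query_position(query, label, offset)
    count <- (slot - 1) + (dom_len - offset + 1) / dom_len
    bin <- if (slot >= 11L) "M11+" else label
    if (classes[i] == "decoy") {
      seqs[i] <- random_dna(lq - p + 1L)
      truth[[i]] <- data.frame(
        locus_id = id, class = "decoy", bin = NA_character_,
        offset = NA_integer_, monomer_count = NA_real_,
        stringsAsFactors = FALSE
      )
      next
    }
    s <- substr(query$sequence, p, lq)
    if (classes[i] == "tether_truncated") {
      cut <- sample(11:max(11L, min(tether_len, 60L)), 1L)
      s <- substr(s, 1L, nchar(s) - cut)
    }
    seqs[i] <- mutate_sequence(
      s, cfg$substitution_rate, cfg$indel_rate, cfg$indel_geom_p
    )
    truth[[i]] <- data.frame(
      locus_id = id, class = classes[i], bin = bin,
      offset = as.integer(offset), monomer_count = count,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  names(seqs) <- truth$locus_id
  list(sequences = seqs, truth = truth, query = query, seed = seed)
}

#' Configuration for reporter-plate simulation
#'
#' Describes a synthetic dual-luciferase plate. Transfection efficiency
#' enters the firefly and Renilla signals identically (that is the point
#' of the internal Renilla control: the per-well ratio cancels it), while
#' measurement noise perturbs each signal independently. Optional dose
#' series scale both signals by `d / (1 + d / sat_K)`, linear in the dose
#' until saturation at half-max `sat_K`.
#'
#' @param strengths named positive vector of true promoter strengths; the
#'   control's strength 1 represents the assay background.
#' @param control name of the no-promoter control construct.
#' @param wells_per_construct replicate wells (default 4).
#' @param efficiency_cv coefficient of variation of the log-normal
#'   per-well transfection efficiency (default 0.3).
#' @param noise_cv coefficient of variation of the log-normal measurement
#'   noise applied independently to each signal (default 0.1).
#' @param doses optional numeric vector of plasmid doses (ng).
#' @param sat_K saturation half-max dose in ng (`Inf` = linear).
#' @param c_fluc,c_rluc instrument scale factors giving raw luminescence
#'   units.
#' @param plate plate id.
#' @return an object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(strengths = c(
                               pLK037 = 1, pCH117 = 914, Tf_II = 394,
                               A_I = 274, Tf_I = 214, Tf_III = 189,
                               A_II = 114, Gf_I = 59
                             ),
                             control = "pLK037",
                             wells_per_construct = 4L,
                             efficiency_cv = 0.3, noise_cv = 0.1,
                             doses = NULL, sat_K = Inf,
                             c_fluc = 135, c_rluc = 25000,
                             plate = "plate1") {
  if (is.null(names(strengths)) || any(!nzchar(names(strengths)))) {
    stop("invalid config: strengths must be named")
  }
  if (any(strengths <= 0)) stop("invalid config: strengths must be > 0")
  if (!(control %in% names(strengths))) {
    stop(sprintf("invalid config: missing control construct '%s'", control))
  }
  if (efficiency_cv < 0 || noise_cv < 0) stop("invalid config: CVs must be >= 0")
  structure(
    list(
      strengths = strengths, control = control,
      wells_per_construct = as.integer(wells_per_construct),
      efficiency_cv = efficiency_cv, noise_cv = noise_cv,
      doses = doses, sat_K = sat_K, c_fluc = c_fluc, c_rluc = c_rluc,
      plate = plate
    ),
    class = "plate_sim_config"
  )
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a dual-luciferase plate
#'
#' Draws `rluc = E * c_rluc * noise` and `fluc = E * c_fluc * strength *
#' noise'` per well, with `E` the shared per-well transfection efficiency
#' and independent measurement noise on each signal; with a dose series,
#' both signals are scaled by the same saturating dose factor, which
#' cancels in the ratio. Reproducible given the seed.
#'
#' @param cfg a [plate_sim_config()].
#' @param seed RNG seed (default 1).
#' @return list with `wells` (data frame `plate`, `well`, `construct`,
#'   `fluc`, `rluc` and, for dose series, `dose`) and `strengths` (the
#'   truth).
#' @export
simulate_plate <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "plate_sim_config"))
  set.seed(seed)
  doses <- if (is.null(cfg$doses)) NA_real_ else cfg$doses
  grid <- expand.grid(
    rep = seq_len(cfg$wells_per_construct),
    construct = names(cfg$strengths),
    dose = doses,
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  eff <- rlnorm_cv(n, cfg$efficiency_cv)
  noise_f <- rlnorm_cv(n, cfg$noise_cv)
  noise_r <- rlnorm_cv(n, cfg$noise_cv)
  dose_factor <- if (is.null(cfg$doses)) {
    rep(1, n)
  } else {
    grid$dose / (1 + grid$dose / cfg$sat_K)
  }
  strength <- cfg$strengths[grid$construct]
  wells <- data.frame(
    plate = cfg$plate,
    well = sprintf("w%03d", seq_len(n)),
    construct = grid$construct,
    fluc = eff * cfg$c_fluc * strength * noise_f * dose_factor,
    rluc = eff * cfg$c_rluc * noise_r * dose_factor,
    stringsAsFactors = FALSE
  )
  if (!is.null(cfg$doses)) wells$dose <- grid$dose
  rownames(wells) <- NULL
  list(wells = wells, strengths = cfg$strengths)
}
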