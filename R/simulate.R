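## In-silico evolution of an MSA down a copy-tree, with exact ground-truth
## bookkeeping of every co-segregating change.
##
## The population starts as copies of a single ancestor and is expanded in
## levels; within each level every lineage undergoes cycles of (i) random
## point mutation, (ii) forced joint mutation of covarion pairs, and (iii)
## zone recombination with a random donor.  Per cycle and lineage the
## changed-position sets are recorded in four count matrices:
##   mutCOV - pairs of positions changed by random point mutation,
##   covCOV - fired covarion pairs plus cross-pairs between distinct
##            covarion pairs fired in the same cycle,
##   recCOV - pairs of positions changed by recombination, plus pairs
##            mixing a mutated and a recombined position,
##   totCOV - the sum of all of the above, accumulated independently.
## A position changed by mutation and then overwritten by recombination in
## the same cycle is attributed to recombination only, so every pair
## increment lands in exactly one component matrix and
## totCOV = mutCOV + covCOV + recCOV holds after every cycle.

#' Build a recombination zone map from crossover points
#'
#' Interior crossover points split the positions 1..n_pos into contiguous
#' half-open zones [1, p1), [p1, p2), ..., [pk, n_pos]; the zone count is
#' the number of interior points plus one.
#'
#' @param points Strictly increasing interior crossover positions, each in
#'   (1, n_pos].  May be empty (single zone).
#' @param n_pos Sequence length.
#' @return Object of class \code{recombination_map}: list with
#'   \code{zones} (list of integer position vectors), \code{points},
#'   \code{n_pos}.
#' @export
zones_from_crossovers <- function(points, n_pos) {
  points <- as.integer(points)
  if (length(points) > 0) {
    if (is.unsorted(points, strictly = TRUE))
      stop("crossover points must be strictly increasing")
    if (any(points <= 1L) || any(points > n_pos))
      stop("crossover points must lie in (1, n_pos]")
  }
  starts <- c(1L, points)
  ends <- c(points - 1L, n_pos)
  zones <- Map(seq.int, starts, ends)
  structure(list(zones = zones, points = points, n_pos = as.integer(n_pos)),
            class = "recombination_map")
}

#' @export
print.recombination_map <- function(x, ...) {
  cat(sprintf("recombination map: %d zones over %d positions\n",
              length(x$zones), x$n_pos))
  invisible(x)
}

#' Simulation configuration
#'
#' Collects and validates all parameters of an evolution run.  Defaults
#' describe a small family: a 3-level copy-tree (3, then +2, then +4
#' copies of each current sequence), 10 mutation/recombination cycles per
#' level, a 0.005 per-position per-cycle mutation probability, covarion
#' pairs firing with probability 0.05 per cycle, and recombination of a
#' random zone with probability 0.1 per lineage per cycle.
#'
#' @param n_pos Alignment length.
#' @param branching Copy counts per level: level 1 creates
#'   \code{branching[1]} copies of the ancestor; each later level k
#'   appends \code{branching[k]} copies of every current sequence (so the
#'   population is multiplied by \code{branching[k] + 1}).
#' @param cycles Mutation/recombination cycles per level (scalar or one
#'   value per level).
#' @param mut_prob Per-position per-cycle probability of a point-mutation
#'   draw at non-covarion positions (a draw may be silent).
#' @param covarion_pairs 2-column integer matrix of forced covarion
#'   position pairs (pairwise disjoint positions), or \code{NULL} to place
#'   \code{n_covarions} disjoint random pairs at run time.
#' @param n_covarions Number of random covarion pairs when
#'   \code{covarion_pairs} is \code{NULL}.
#' @param cov_prob Per-pair per-cycle probability that a covarion pair
#'   fires (draws jointly from its pair distribution).
#' @param covarion_states Optional list (one element per pair) of 21 x 21
#'   joint probability tables over the alphabet; by default each pair gets
#'   a coupled model of \code{cov_states} residue couples with equal
#'   probability, drawn at run time.
#' @param cov_states Number of residue couples in the default coupled
#'   covarion model (default 8).
#' @param crossovers Interior crossover points (see
#'   \code{\link{zones_from_crossovers}}); empty for a single zone.
#' @param rec_prob Per-lineage per-cycle probability of receiving one
#'   random zone from a random donor lineage.
#' @param n_seq Target number of sequences; the final population is
#'   subsampled (uniform, without replacement, seeded) down to this.
#'   \code{NULL} keeps everything.
#' @param profile Optional 20 x n_pos (or 21 x n_pos) matrix of
#'   position-specific residue probabilities used for the ancestor and for
#'   mutation draws; default uniform over the 20 amino acids.
#' @param ancestor Optional explicit ancestor sequence (character vector
#'   of length n_pos); overrides profile sampling.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_pos,
                       branching = c(3L, 2L, 4L),
                       cycles = 10L,
                       mut_prob = 0.005,
                       covarion_pairs = NULL,
                       n_covarions = 0L,
                       cov_prob = 0.05,
                       covarion_states = NULL,
                       cov_states = 8L,
                       crossovers = integer(0),
                       rec_prob = 0.1,
                       n_seq = NULL,
                       profile = NULL,
                       ancestor = NULL) {
  n_pos <- as.integer(n_pos)
  stopifnot(n_pos >= 2L, length(branching) >= 1L, all(branching >= 1L))
  cycles <- as.integer(cycles)
  if (length(cycles) == 1L) cycles <- rep(cycles, length(branching))
  stopifnot(length(cycles) == length(branching), all(cycles >= 0L))
  stopifnot(mut_prob >= 0, mut_prob <= 1, cov_prob >= 0, cov_prob <= 1,
            rec_prob >= 0, rec_prob <= 1)
  if (!is.null(covarion_pairs)) {
    covarion_pairs <- matrix(as.integer(covarion_pairs), ncol = 2L)
    pos <- as.vector(covarion_pairs)
    if (anyDuplicated(pos))
      stop("covarion positions must be pairwise disjoint")
    if (any(pos < 1L) || any(pos > n_pos))
      stop("covarion positions out of range")
    n_covarions <- nrow(covarion_pairs)
  }
  zones_from_crossovers(crossovers, n_pos)  # validates
  if (!is.null(profile)) {
    profile <- as.matrix(profile)
    if (nrow(profile) == 20L)
      profile <- rbind(profile, 0)
    if (nrow(profile) != ALPHA_N || ncol(profile) != n_pos)
      stop("profile must be 20 (or 21) x n_pos")
    cs <- colSums(profile)
    if (any(abs(cs - 1) > 1e-6)) stop("profile columns must sum to 1")
  }
  if (!is.null(ancestor)) {
    ancestor <- normalize_symbols(as.character(ancestor))
    if (length(ancestor) != n_pos) stop("ancestor length != n_pos")
  }
  if (!is.null(covarion_states)) {
    if (length(covarion_states) != n_covarions)
      stop("need one joint table per covarion pair")
    for (tb in covarion_states) {
      if (!all(dim(as.matrix(tb)) == c(ALPHA_N, ALPHA_N)) ||
          abs(sum(tb) - 1) > 1e-6)
        stop("each covarion state table must be 21 x 21 and sum to 1")
    }
  }
  structure(list(n_pos = n_pos, branching = as.integer(branching),
                 cycles = cycles, mut_prob = mut_prob,
                 covarion_pairs = covarion_pairs,
                 n_covarions = as.integer(n_covarions),
                 cov_prob = cov_prob, covarion_states = covarion_states,
                 cov_states = as.integer(cov_states),
                 crossovers = as.integer(crossovers), rec_prob = rec_prob,
                 n_seq = if (is.null(n_seq)) NULL else as.integer(n_seq),
                 profile = profile, ancestor = ancestor),
            class = "sim_config")
}

#' Sample an ancestor sequence
#'
#' Draws one residue per position from the configuration's
#' position-specific profile (uniform over the 20 amino acids when no
#' profile is given), or returns the explicit ancestor if one is set.
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return Character vector of length \code{n_pos}.
#' @export
sample_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$ancestor)) return(cfg$ancestor)
  if (is.null(cfg$profile))
    return(sample(MSA_ALPHABET[1:20], cfg$n_pos, replace = TRUE))
  vapply(seq_len(cfg$n_pos), function(j)
    sample(MSA_ALPHABET, 1L, prob = cfg$profile[, j]), character(1))
}

#' Jointly mutate a covarion pair
#'
#' Draws a residue couple from a 21 x 21 joint probability table (rows =
#' symbol at the first position, columns = symbol at the second) and
#' returns the two residues.
#'
#' @param joint 21 x 21 probability table summing to 1.
#' @return Character vector of length 2.
#' @export
mutate_covarion_pair <- function(joint) {
  joint <- as.matrix(joint)
  k <- sample.int(ALPHA_N * ALPHA_N, 1L, prob = as.vector(joint))
  i <- (k - 1L) %% ALPHA_N + 1L       # row index (column-major vector)
  j <- (k - 1L) %/% ALPHA_N + 1L
  c(MSA_ALPHABET[i], MSA_ALPHABET[j])
}

#' Recombine one zone from a donor into an acceptor sequence
#'
#' Picks one zone of the map uniformly at random and replaces the
#' acceptor's residues in that zone by the donor's.
#'
#' @param acceptor,donor Character vectors of equal length.
#' @param map A \code{\link{zones_from_crossovers}} map.
#' @return List with \code{sequence} (the recombinant) and
#'   \code{changed} (positions in the zone where donor differed).
#' @export
recombine <- function(acceptor, donor, map) {
  stopifnot(length(acceptor) == length(donor),
            inherits(map, "recombination_map"),
            length(acceptor) == map$n_pos)
  z <- map$zones[[sample.int(length(map$zones), 1L)]]
  changed <- z[donor[z] != acceptor[z]]
  acceptor[z] <- donor[z]
  list(sequence = acceptor, changed = changed)
}

## Default coupled joint table: n_states residue couples with equal
## probability, distinct at both positions (perfect coupling; each draw
## of the pair lands on one couple).
coupled_joint <- function(n_states = 8L) {
  a <- sample.int(20L, n_states)
  b <- sample.int(20L, n_states)
  tb <- matrix(0, ALPHA_N, ALPHA_N)
  tb[cbind(a, b)] <- 1 / n_states
  tb
}

## Add +1 to mat at every unordered pair (i_idx[k], j_idx[k]), symmetric.
add_pairs <- function(mat, i_idx, j_idx) {
  mat[cbind(i_idx, j_idx)] <- mat[cbind(i_idx, j_idx)] + 1L
  mat[cbind(j_idx, i_idx)] <- mat[cbind(j_idx, i_idx)] + 1L
  mat
}

## All unordered pairs within a position set, as a 2-row matrix (or NULL).
pairs_within <- function(pos) {
  if (length(pos) < 2L) return(NULL)
  utils::combn(sort(pos), 2L)
}

## Covarion pair increments: the fired pairs themselves plus all cross
## pairs between positions of distinct fired pairs.
covarion_pair_increments <- function(fired_pairs) {
  if (nrow(fired_pairs) == 0L) return(NULL)
  out_i <- fired_pairs[, 1]; out_j <- fired_pairs[, 2]
  k <- nrow(fired_pairs)
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      pa <- fired_pairs[a, ]; pb <- fired_pairs[b, ]
      cross <- expand.grid(pa, pb)
      out_i <- c(out_i, cross[, 1]); out_j <- c(out_j, cross[, 2])
    }
  }
  rbind(out_i, out_j)
}

#' Evolve an alignment from a single ancestor
#'
#' Runs the full copy-tree simulation described in
#' \code{\link{sim_config}} and returns the final alignment together with
#' the ground-truth evolution record.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Integer seed; all randomness in the run flows from it.
#' @return List of class \code{evolution} with elements:
#'   \describe{
#'     \item{msa}{the final \code{msa} (subsampled to \code{n_seq} if
#'       requested; row order follows construction order);}
#'     \item{record}{class \code{evolution_record}: \code{totCOV},
#'       \code{mutCOV}, \code{covCOV}, \code{recCOV} integer matrices,
#'       \code{covarion_pairs}, \code{events} (one row per mechanism
#'       event: level, cycle, lineage, mechanism, comma-separated
#'       positions), \code{cycle_residual} (max abs elementwise residual
#'       of totCOV - mutCOV - covCOV - recCOV after each completed global
#'       cycle), \code{seed}, and the \code{config}.}}
#' @export
evolve_msa <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  p <- cfg$n_pos
  map <- zones_from_crossovers(cfg$crossovers, p)

  ## covarion placement and pair distributions
  pairs <- cfg$covarion_pairs
  if (is.null(pairs) && cfg$n_covarions > 0L) {
    pos <- sample.int(p, 2L * cfg$n_covarions)
    pairs <- matrix(pos, ncol = 2L)
    pairs <- t(apply(pairs, 1L, sort))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
  n_cov <- nrow(pairs)
  states <- cfg$covarion_states
  if (is.null(states) && n_cov > 0L)
    states <- replicate(n_cov, coupled_joint(cfg$cov_states), simplify = FALSE)
  cov_pos <- as.vector(pairs)
  free_pos <- setdiff(seq_len(p), cov_pos)   # point mutations avoid covarions

  mutCOV <- matrix(0L, p, p); covCOV <- matrix(0L, p, p)
  recCOV <- matrix(0L, p, p); totCOV <- matrix(0L, p, p)

  ancestor <- sample_ancestor(cfg)
  ## initialize covarion positions from their own pair distributions so
  ## the ancestor is consistent with the coupled model
  for (k in seq_len(n_cov)) {
    rr <- mutate_covarion_pair(states[[k]])
    ancestor[pairs[k, 1]] <- rr[1]
    ancestor[pairs[k, 2]] <- rr[2]
  }

  pop <- list()
  events <- list(); ev_n <- 0L
  cycle_residual <- numeric(0)
  add_event <- function(level, cycle, lineage, mech, positions) {
    ev_n <<- ev_n + 1L
    events[[ev_n]] <<- data.frame(
      level = level, cycle = cycle, lineage = lineage, mechanism = mech,
      positions = paste(positions, collapse = ","),
      stringsAsFactors = FALSE)
  }

  draw_residues <- function(positions) {
    if (is.null(cfg$profile)) {
      MSA_ALPHABET[sample.int(20L, length(positions), replace = TRUE)]
    } else {
      vapply(positions, function(j)
        sample(MSA_ALPHABET, 1L, prob = cfg$profile[, j]), character(1))
    }
  }

  for (lev in seq_along(cfg$branching)) {
    b <- cfg$branching[lev]
    if (lev == 1L) {
      pop <- replicate(b, ancestor, simplify = FALSE)
    } else {
      pop <- c(pop, pop[rep(seq_along(pop), times = b)])
    }
    n_lin <- length(pop)
    for (cyc in seq_len(cfg$cycles[lev])) {
      snapshot <- pop   # donors for recombination come from cycle start
      for (ln in seq_len(n_lin)) {
        sq <- pop[[ln]]
        ## (i) point mutations at non-covarion positions
        M <- integer(0)
        if (cfg$mut_prob > 0 && length(free_pos) > 0L) {
          hit <- free_pos[stats::runif(length(free_pos)) < cfg$mut_prob]
          if (length(hit) > 0L) {
            new <- draw_residues(hit)
            chg <- hit[new != sq[hit]]
            sq[hit] <- new
            M <- chg
          }
        }
        ## (ii) covarion pairs
        fired <- matrix(integer(0), ncol = 2L)
        if (n_cov > 0L && cfg$cov_prob > 0) {
          fire <- which(stats::runif(n_cov) < cfg$cov_prob)
          fired_list <- integer(0)
          for (k in fire) {
            rr <- mutate_covarion_pair(states[[k]])
            if (rr[1] != sq[pairs[k, 1]] || rr[2] != sq[pairs[k, 2]]) {
              sq[pairs[k, 1]] <- rr[1]
              sq[pairs[k, 2]] <- rr[2]
              fired_list <- c(fired_list, k)
            }
          }
          fired <- pairs[fired_list, , drop = FALSE]
        }
        ## (iii) recombination
        R <- integer(0)
        if (cfg$rec_prob > 0 && n_lin > 1L &&
            stats::runif(1L) < cfg$rec_prob) {
          donor <- sample(setdiff(seq_len(n_lin), ln), 1L)
          rec <- recombine(sq, snapshot[[donor]], map)
          sq <- rec$sequence
          R <- rec$changed
        }
        pop[[ln]] <- sq
        ## bookkeeping: recombination wins mixed attribution
        M <- setdiff(M, R)
        if (length(M) > 0L) {
          pw <- pairs_within(M)
          if (!is.null(pw)) {
            mutCOV <- add_pairs(mutCOV, pw[1, ], pw[2, ])
            totCOV <- add_pairs(totCOV, pw[1, ], pw[2, ])
          }
          add_event(lev, cyc, ln, "mutation", M)
        }
        ci <- covarion_pair_increments(fired)
        if (!is.null(ci)) {
          covCOV <- add_pairs(covCOV, ci[1, ], ci[2, ])
          totCOV <- add_pairs(totCOV, ci[1, ], ci[2, ])
          for (k in seq_len(nrow(fired)))
            add_event(lev, cyc, ln, "covarion", fired[k, ])
        }
        if (length(R) > 0L) {
          pr <- pairs_within(R)
          if (!is.null(pr)) {
            recCOV <- add_pairs(recCOV, pr[1, ], pr[2, ])
            totCOV <- add_pairs(totCOV, pr[1, ], pr[2, ])
          }
          if (length(M) > 0L) {
            cross <- expand.grid(M, R)
            recCOV <- add_pairs(recCOV, cross[, 1], cross[, 2])
            totCOV <- add_pairs(totCOV, cross[, 1], cross[, 2])
          }
          add_event(lev, cyc, ln, "recombination", R)
        }
      }
      cycle_residual <- c(cycle_residual,
                          max(abs(totCOV - mutCOV - covCOV - recCOV)))
    }
  }

  seqs <- do.call(rbind, pop)
  if (!is.null(cfg$n_seq)) {
    if (cfg$n_seq > nrow(seqs))
      stop("target n_seq (", cfg$n_seq, ") exceeds final population (",
           nrow(seqs), "); increase branching")
    ## keep sample() order: the returned alignment rows are a uniform
    ## random draw, not grouped by construction order
    keep <- sample.int(nrow(seqs), cfg$n_seq)
    seqs <- seqs[keep, , drop = FALSE]
  }
  aln <- as_msa(seqs, ids = sprintf("seq%04d", seq_len(nrow(seqs))))
  ev <- if (ev_n > 0L) do.call(rbind, events) else
    data.frame(level = integer(0), cycle = integer(0), lineage = integer(0),
               mechanism = character(0), positions = character(0))
  record <- structure(
    list(totCOV = totCOV, mutCOV = mutCOV, covCOV = covCOV, recCOV = recCOV,
         covarion_pairs = pairs, covarion_states = states,
         events = ev, cycle_residual = cycle_residual,
         seed = as.integer(seed), config = cfg),
    class = "evolution_record")
  structure(list(msa = aln, record = record), class = "evolution")
}

#' @export
print.evolution_record <- function(x, ...) {
  cat(sprintf(
    "evolution record: %d covarion pairs, %d events, totCOV sum %d\n",
    nrow(x$covarion_pairs), nrow(x$events), sum(x$totCOV)))
  invisible(x)
}

#' Rebuild the count matrices from an evolution record's event log
#'
#' Replays the event log (optionally only events up to a given global
#' cycle index) and reconstructs the four count matrices using the same
#' counting contract as \code{\link{evolve_msa}}.  Used to audit the
#' matrices the simulator accumulated online.
#'
#' @param record An \code{evolution_record}.
#' @return List with \code{totCOV}, \code{mutCOV}, \code{covCOV},
#'   \code{recCOV}.
#' @export
replay_events <- function(record) {
  p <- nrow(record$totCOV)
  mutCOV <- matrix(0L, p, p); covCOV <- matrix(0L, p, p)
  recCOV <- matrix(0L, p, p)
  ev <- record$events
  if (nrow(ev) > 0L) {
    key <- paste(ev$level, ev$cycle, ev$lineage)
    for (g in unique(key)) {
      sub <- ev[key == g, , drop = FALSE]
      poslist <- lapply(strsplit(sub$positions, ","), as.integer)
      M <- unlist(poslist[sub$mechanism == "mutation"])
      R <- unlist(poslist[sub$mechanism == "recombination"])
      fired <- do.call(rbind, poslist[sub$mechanism == "covarion"])
      pw <- pairs_within(M)
      if (!is.null(pw)) mutCOV <- add_pairs(mutCOV, pw[1, ], pw[2, ])
      if (!is.null(fired)) {
        ci <- covarion_pair_increments(fired)
        covCOV <- add_pairs(covCOV, ci[1, ], ci[2, ])
      }
      pr <- pairs_within(R)
      if (!is.null(pr)) recCOV <- add_pairs(recCOV, pr[1, ], pr[2, ])
      if (length(M) > 0L && length(R) > 0L) {
        cross <- expand.grid(M, R)
        recCOV <- add_pairs(recCOV, cross[, 1], cross[, 2])
      }
    }
  }
  list(totCOV = mutCOV + covCOV + recCOV, mutCOV = mutCOV,
       covCOV = covCOV, recCOV = recCOV)
}

#' Correlation between reference and simulated entropy profiles
#'
#' Statistical-fidelity diagnostic: when a run used a reference-derived
#' profile, compares the per-column relative entropy of the simulated
#' alignment with that of a reference alignment.
#'
#' @param sim_aln Simulated \code{msa}.
#' @param ref_aln Reference \code{msa} of the same width.
#' @param background Passed to \code{\link{relative_entropy}}.
#' @return Pearson correlation of the two profiles.
#' @export
profile_fidelity <- function(sim_aln, ref_aln,
                             background = rep(1 / 20, 20)) {
  stats::cor(as.numeric(relative_entropy(sim_aln, background)),
             as.numeric(relative_entropy(ref_aln, background)))
}

#' Preset configuration for a recombination-free clustered family
#'
#' A \code{\link{sim_config}} describing a family evolved purely down a
#' copy-tree (no recombination): five deeply diverged subfamilies
#' (saturated between-subfamily divergence) of 120 close homologs each,
#' subsampled to 600 sequences of 150 positions with 8 covarion pairs.
#' This is the study condition under which the resorting diagnostics
#' (entropy, joint entropy and mutual information of the differential
#' binary translation) are characterized.
#'
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
tree_family_config <- function(...) {
  defaults <- list(
    n_pos = 150L,
    branching = c(5L, 119L),
    cycles = c(280L, 5L),
    mut_prob = 0.021,
    n_covarions = 8L,
    cov_prob = 0.05,
    rec_prob = 0,
    n_seq = 600L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Preset configuration modelled on a 280-residue family
#'
#' A ready-made \code{\link{sim_config}} mirroring the KDO8P-synthase-like
#' study conditions: 300 sequences of 280 positions, 28 covarion pairs,
#' and 9 recombination zones (interior crossovers 20, 61, 89, 167, 193,
#' 216, 235, 259).
#'
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
kdo8ps_like_config <- function(...) {
  defaults <- list(
    n_pos = 280L,
    branching = c(5L, 59L),          # 5 deep subfamilies of 60 sequences
    cycles = c(280L, 5L),            # saturated deep branches, tight clades
    mut_prob = 0.021,
    n_covarions = 28L,
    cov_prob = 0.05,
    crossovers = c(20L, 61L, 89L, 167L, 193L, 216L, 235L, 259L),
    rec_prob = 0.02,
    n_seq = 300L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
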