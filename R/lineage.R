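## Somatic-hypermutation lineage simulation.
##
## Substitution-only model over the full rearranged sequence (fixed length
## across a lineage). Two modes are provided: a generic branching process
## (`simulate_lineage`) and a study-shaped generator
## (`simulate_clone_groups`) that produces a prescribed number of
## CDR3-defined subclone groups with exact ground-truth labels.
##
## The mutation engine carries two biological features of germinal-center
## clones: a CDR mutation-density bias (hypermutation clusters in the CDRs)
## and antigen-selection shaping, implemented as probabilistic vetoes of
## framework replacement mutations (BCR structure is conserved) and of CDR
## silent mutations (antigen-driven enrichment of replacements). The default
## veto strengths are calibrated so the expected replacement/silent ratios
## match the observed values in follicular neoplasia: about 1.8 in the
## frameworks (below the 2.845 germline expectation) and about 11 in the
## CDRs. Setting both vetoes to 0 recovers a neutral uniform/biased
## substitution process.

FR_REPLACEMENT_VETO_DEFAULT <- 0.4
CDR_SILENT_VETO_DEFAULT <- 0.73
CDR_BIAS_DEFAULT <- 3
J_SHM_WEIGHT_DEFAULT <- 0.3

## Region intervals of a full rearranged sequence (V start = position 1).
full_region_map <- function(junction_length, j_trim = J_TRIM_DEFAULT) {
  vb <- v_region_bounds()
  v_end <- max(vb$end)
  cdr3_end <- v_end + junction_length + 3L
  j_end <- v_end + junction_length + (J_LENGTH - j_trim)
  dplyr::bind_rows(
    vb,
    tibble::tibble(region = c("CDR3", "J"),
                   start = c(v_end + 1L, cdr3_end + 1L),
                   end = c(cdr3_end, j_end))
  )
}

region_of_positions <- function(positions, region_map) {
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(region_map))) {
    hit <- positions >= region_map$start[i] & positions <= region_map$end[i]
    out[hit] <- region_map$region[i]
  }
  out
}

## Positions of the full rearrangement observable after primer trimming and
## N-gap masking in the default paired-end design.
observable_positions <- function(ref, junction_length, read_length = 112L) {
  v_off <- ref$design$v_amplicon_start - 1L
  amp_len <- (V_LENGTH - v_off) + junction_length + (J_LENGTH - J_TRIM_DEFAULT)
  p <- nchar(ref$primers$forward)
  q <- nchar(ref$primers$reverse)
  amp_pos <- c(seq.int(p + 1L, read_length),
               seq.int(amp_len - read_length + 1L, amp_len - q))
  amp_pos + v_off
}

cdr3_interval <- function(junction_length) {
  c(V_LENGTH + 1L, V_LENGTH + junction_length + 3L)
}

cdr3_aa_of <- function(sequence, junction_length) {
  iv <- cdr3_interval(junction_length)
  translate_nt(substr(sequence, iv[1], iv[2]))
}

## Is the single-base change pos/to a replacement (R), silent (S) or outside
## a complete codon ("unclassified") with respect to `sequence`?
rs_of_change <- function(sequence, pos, to) {
  cs <- pos - (pos - 1L) %% 3L
  if (cs + 2L > nchar(sequence)) return("unclassified")
  codon <- substr(sequence, cs, cs + 2L)
  mutated <- str_assign(codon, pos - cs + 1L, to)
  if (grepl("[^ACGT]", codon)) return("unclassified")
  if (translate_nt(codon) == translate_nt(mutated)) "S" else "R"
}

creates_stop <- function(sequence, pos, to) {
  cs <- pos - (pos - 1L) %% 3L
  if (cs + 2L > nchar(sequence)) return(FALSE)
  codon <- str_assign(substr(sequence, cs, cs + 2L), pos - cs + 1L, to)
  codon %in% STOP_CODONS
}

## Selection veto probability for a candidate change.
veto_prob <- function(region, rs, fr_replacement_veto, cdr_silent_veto) {
  if (is.na(region) || rs == "unclassified") return(0)
  if (region %in% c("FR1", "FR2", "FR3") && rs == "R") return(fr_replacement_veto)
  if (region %in% c("CDR1", "CDR2", "CDR3") && rs == "S") return(cdr_silent_veto)
  0
}

## Per-site Bernoulli mutation draw (generic mode). Vetoed candidates are
## dropped. Returns list(sequence, mutations tibble).
draw_mutations_bernoulli <- function(sequence, rate, weights, region_map,
                                     fr_replacement_veto, cdr_silent_veto) {
  L <- nchar(sequence)
  p <- pmin(rate * weights, 1)
  hits <- which(runif(L) < p)
  muts <- list()
  for (pos in hits) {
    from <- substr(sequence, pos, pos)
    to <- sample(setdiff(DNA_BASES, from), 1L)
    reg <- region_of_positions(pos, region_map)
    rs <- rs_of_change(sequence, pos, to)
    if (runif(1) < veto_prob(reg, rs, fr_replacement_veto, cdr_silent_veto)) next
    sequence <- str_assign(sequence, pos, to)
    muts[[length(muts) + 1L]] <- tibble::tibble(position = pos, from = from, to = to)
  }
  list(sequence = sequence,
       mutations = if (length(muts)) dplyr::bind_rows(muts) else
         tibble::tibble(position = integer(), from = character(), to = character()))
}

## Draw exactly n accepted mutations at distinct positions from `allowed`
## (study mode). Stop-creating changes are redrawn; vetoed changes redrawn.
draw_mutations_exact <- function(sequence, n, allowed, weights, region_map,
                                 fr_replacement_veto, cdr_silent_veto,
                                 forbid_stops = TRUE, max_tries = 10000L) {
  muts <- list()
  used <- integer(0)
  tries <- 0L
  while (length(muts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place the requested mutations")
    avail <- setdiff(allowed, used)
    if (!length(avail)) stop("no mutable positions left")
    pos <- if (length(avail) == 1L) avail else
      sample(avail, 1L, prob = weights[match(avail, allowed)])
    from <- substr(sequence, pos, pos)
    to <- sample(setdiff(DNA_BASES, from), 1L)
    if (forbid_stops && creates_stop(sequence, pos, to)) next
    reg <- region_of_positions(pos, region_map)
    rs <- rs_of_change(sequence, pos, to)
    if (runif(1) < veto_prob(reg, rs, fr_replacement_veto, cdr_silent_veto)) next
    sequence <- str_assign(sequence, pos, to)
    used <- c(used, pos)
    muts[[length(muts) + 1L]] <- tibble::tibble(position = pos, from = from, to = to)
  }
  list(sequence = sequence,
       mutations = if (length(muts)) dplyr::bind_rows(muts) else
         tibble::tibble(position = integer(), from = character(), to = character()))
}

## Per-site SHM weights: CDRs are hypermutation-biased; the J segment sees a
## reduced rate (SHM targeting decays sharply 3' of the V segment).
site_weights <- function(L, region_map, cdr_bias, j_shm_weight = J_SHM_WEIGHT_DEFAULT) {
  w <- rep(1, L)
  cdr <- region_map[region_map$region %in% c("CDR1", "CDR2", "CDR3"), ]
  for (i in seq_len(nrow(cdr))) {
    w[cdr$start[i]:cdr$end[i]] <- cdr_bias
  }
  jr <- region_map[region_map$region == "J", ]
  for (i in seq_len(nrow(jr))) {
    w[jr$start[i]:jr$end[i]] <- j_shm_weight
  }
  w
}

new_lineage_tibble <- function() {
  tibble::tibble(node_id = character(), parent_id = character(),
                 generation = integer(), sequence = character(),
                 mutations = list(), cdr3_aa = character(),
                 group_id = character(), productive = logical(),
                 n_from_founder = integer())
}

#' Simulate an SHM lineage as a branching process
#'
#' Starting from the naive recombination of the founder alleles, each node in
#' each round spawns `n_children` children; every child acquires independent
#' per-site substitutions at `mutation_rate` per site per round, with the CDR
#' density bias and selection vetoes described in the package vignette.
#' Sequence length is constant across the lineage (substitution-only model).
#'
#' @param ref A `germline_set`.
#' @param founder A [founder_spec()].
#' @param n_rounds Number of mutation/division rounds.
#' @param mutation_rate Per-site, per-round substitution probability.
#' @param n_children Children per node per round.
#' @param cdr_bias Mutation-density multiplier inside CDR1/2/3.
#' @param j_shm_weight Relative SHM rate over the J segment (SHM targeting
#'   decays 3' of V); 1 restores a uniform rate.
#' @param fr_replacement_veto Probability that a framework replacement
#'   mutation is vetoed (structural selection); 0 disables.
#' @param cdr_silent_veto Probability that a CDR silent mutation is vetoed
#'   (antigen selection); 0 disables.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A `clone_lineage` tibble (one row per node: `node_id`,
#'   `parent_id`, `generation`, `sequence`, `mutations` list-column,
#'   `cdr3_aa`, `group_id`, `productive`, `n_from_founder`), with the naive
#'   germline recombinant, founder spec and junction length as attributes.
#' @export
#' @examples
#' ref <- build_germline_set(seed = 1)
#' lin <- simulate_lineage(ref, n_rounds = 1, mutation_rate = 0.01, seed = 7)
#' nrow(lin)
simulate_lineage <- function(ref, founder = founder_spec(), n_rounds = 2,
                             mutation_rate = 0.002, n_children = 2,
                             cdr_bias = CDR_BIAS_DEFAULT,
                             j_shm_weight = J_SHM_WEIGHT_DEFAULT,
                             fr_replacement_veto = FR_REPLACEMENT_VETO_DEFAULT,
                             cdr_silent_veto = CDR_SILENT_VETO_DEFAULT,
                             seed) {
  stopifnot(!missing(seed), mutation_rate >= 0, mutation_rate <= 1, n_rounds >= 0)
  set.seed(child_seed(seed, 2L))
  naive <- recombine_segments(ref, founder)
  jl <- nchar(founder$junction)
  rmap <- full_region_map(jl, founder$j_trim)
  w <- site_weights(nchar(naive), rmap, cdr_bias, j_shm_weight)

  nodes <- list(list(node_id = "N0001", parent_id = NA_character_, generation = 0L,
                     sequence = naive,
                     mutations = tibble::tibble(position = integer(),
                                                from = character(), to = character())))
  frontier <- 1L
  for (round in seq_len(n_rounds)) {
    next_frontier <- integer(0)
    for (i in frontier) {
      for (k in seq_len(n_children)) {
        res <- draw_mutations_bernoulli(nodes[[i]]$sequence, mutation_rate, w,
                                        rmap, fr_replacement_veto, cdr_silent_veto)
        id <- sprintf("N%04d", length(nodes) + 1L)
        nodes[[length(nodes) + 1L]] <- list(node_id = id,
                                            parent_id = nodes[[i]]$node_id,
                                            generation = round,
                                            sequence = res$sequence,
                                            mutations = res$mutations)
        next_frontier <- c(next_frontier, length(nodes))
      }
    }
    frontier <- next_frontier
  }

  lin <- tibble::tibble(
    node_id = vapply(nodes, `[[`, character(1), "node_id"),
    parent_id = vapply(nodes, `[[`, character(1), "parent_id"),
    generation = vapply(nodes, `[[`, integer(1), "generation"),
    sequence = vapply(nodes, `[[`, character(1), "sequence"),
    mutations = lapply(nodes, `[[`, "mutations")
  )
  lin$cdr3_aa <- cdr3_aa_of(lin$sequence, jl)
  lin$group_id <- paste0("T", match(lin$cdr3_aa, unique(lin$cdr3_aa)))
  lin$productive <- !grepl("\\*", translate_nt(lin$sequence))
  lin$n_from_founder <- hamming(lin$sequence, lin$sequence[1])
  as_clone_lineage(lin, naive = naive, founder = founder, junction_length = jl)
}

as_clone_lineage <- function(lin, naive, founder, junction_length) {
  structure(lin, naive_sequence = naive, founder_spec = founder,
            junction_length = junction_length,
            class = c("clone_lineage", class(tibble::tibble())))
}

#' Simulate a study-shaped clonal lineage with prescribed CDR3 groups
#'
#' Builds a founder clone carrying an archival SHM load (`founder_mutations`
#' substitutions relative to the naive germline recombinant) and exactly
#' `n_groups` CDR3-defined subclone groups: the founder's own group plus
#' engineered groups whose CDR3 amino-acid sequences differ from the
#' founder's at 1-3 positions (never touching the N-X-S/T sequon, so every
#' productive group retains it). The last `n_unproductive` groups
#' additionally carry an engineered FR3 stop codon. Within a group, members
#' radiate from the group founder with 1-3 private substitutions. All
#' mutations in this mode are placed at positions observable after primer
#' trimming and N-gap masking, so ground-truth labels survive the sequencing
#' design exactly.
#'
#' @inheritParams simulate_lineage
#' @param n_groups Total number of CDR3 groups (>= 1).
#' @param n_unproductive How many groups carry an engineered stop codon.
#' @param group_sizes Integer vector of member counts per group; defaults to
#'   the 11-group profile of the emulated study (sizes 1-31 totalling 97
#'   unique sequences) or a geometric profile for other `n_groups`.
#' @param founder_mutations Substitutions separating the founder from the
#'   germline recombinant.
#' @param member_mutation_range Range of private substitutions per additional
#'   group member.
#' @param branch_mutation_range Range of extra non-CDR3 substitutions given
#'   to each engineered group founder (tree branch lengths).
#' @param group_parent `"any"` (default): each engineered group descends
#'   from a randomly chosen earlier group, giving a nested genealogy;
#'   `"founder"`: all groups radiate from the founder, which bounds the
#'   per-sequence mutation load at `founder_mutations` plus one group's
#'   engineering.
#' @param read_length Sequencer read length defining the observable windows.
#' @return A `clone_lineage` tibble as in [simulate_lineage()], plus a
#'   `groups_truth` attribute (tibble: `group_id`, `cdr3_aa`, `productive`,
#'   `n_members`).
#' @export
simulate_clone_groups <- function(ref, founder = founder_spec(), n_groups = 11,
                                  n_unproductive = 3, group_sizes = NULL,
                                  founder_mutations = 20,
                                  member_mutation_range = c(1, 3),
                                  branch_mutation_range = c(1, 4),
                                  group_parent = c("any", "founder"),
                                  cdr_bias = CDR_BIAS_DEFAULT,
                                  j_shm_weight = J_SHM_WEIGHT_DEFAULT,
                                  fr_replacement_veto = FR_REPLACEMENT_VETO_DEFAULT,
                                  cdr_silent_veto = CDR_SILENT_VETO_DEFAULT,
                                  read_length = 112L, seed) {
  group_parent <- match.arg(group_parent)
  stopifnot(!missing(seed), n_groups >= 1, n_unproductive >= 0,
            n_unproductive < n_groups || (n_groups == 1 && n_unproductive == 0))
  set.seed(child_seed(seed, 3L))
  if (is.null(group_sizes)) {
    group_sizes <- if (n_groups == 11L) {
      c(31L, 18L, 12L, 9L, 7L, 5L, 4L, 3L, 3L, 2L, 3L)
    } else {
      pmax(1L, as.integer(round(31 * 0.58^(seq_len(n_groups) - 1L))))
    }
  }
  stopifnot(length(group_sizes) == n_groups, all(group_sizes >= 1))

  naive <- recombine_segments(ref, founder)
  jl <- nchar(founder$junction)
  rmap <- full_region_map(jl, founder$j_trim)
  obs <- observable_positions(ref, jl, read_length)
  cdr3 <- cdr3_interval(jl)
  obs_noncdr3 <- setdiff(obs, seq.int(cdr3[1], cdr3[2]))
  ## keep the engineered-stop codon out of the general mutation pool
  stop_codon_start <- V_LENGTH - 17L   # FR3, observable, codon-aligned (288 %% 3 == 0)
  stopifnot((stop_codon_start - 1L) %% 3L == 0L,
            all(seq.int(stop_codon_start, stop_codon_start + 2L) %in% obs_noncdr3))
  pool <- setdiff(obs_noncdr3, seq.int(stop_codon_start, stop_codon_start + 2L))
  w_pool <- site_weights(nchar(naive), rmap, cdr_bias, j_shm_weight)[pool]

  ## founder node: archival SHM load
  res <- draw_mutations_exact(naive, founder_mutations, pool, w_pool, rmap,
                              fr_replacement_veto, cdr_silent_veto)
  founder_seq <- res$sequence
  founder_cdr3 <- cdr3_aa_of(founder_seq, jl)

  ## CDR3 amino-acid positions free for group engineering: insert-encoded
  ## positions (the final CDR3 residue comes from J), minus the sequon.
  n_insert_aa <- jl %/% 3L
  sequon_at <- as.integer(regexpr("N[^X][ST]", founder_cdr3))
  protected <- if (sequon_at > 0) seq.int(sequon_at, sequon_at + 2L) else integer(0)
  free_aa <- setdiff(seq_len(n_insert_aa), protected)
  founder_cdr3_chars <- strsplit(founder_cdr3, "")[[1]]

  nodes <- list()
  add_node <- function(node_id, parent_id, generation, sequence, parent_seq,
                       group, productive) {
    d <- which(strsplit(sequence, "")[[1]] != strsplit(parent_seq, "")[[1]])
    muts <- tibble::tibble(position = d,
                           from = substring(parent_seq, d, d),
                           to = substring(sequence, d, d))
    nodes[[length(nodes) + 1L]] <<- list(node_id = node_id, parent_id = parent_id,
                                         generation = generation, sequence = sequence,
                                         mutations = muts, group = group,
                                         productive = productive)
  }

  seen <- character(0)
  group_cdr3 <- character(n_groups)
  group_founder_id <- character(n_groups)
  node_counter <- 0L
  next_id <- function() {
    node_counter <<- node_counter + 1L
    sprintf("N%04d", node_counter)
  }

  insert_start <- V_LENGTH + 1L
  engineer_cdr3 <- function(base_seq, target_aa_chars) {
    s <- base_seq
    for (p in seq_len(n_insert_aa)) {
      if (target_aa_chars[p] != founder_cdr3_chars[p]) {
        cs <- insert_start + 3L * (p - 1L)
        s <- paste0(substr(s, 1L, cs - 1L), AA_CODON[[target_aa_chars[p]]],
                    substr(s, cs + 3L, nchar(s)))
      } else {
        ## restore the founder codon in case the parent chain altered it
        cs <- insert_start + 3L * (p - 1L)
        s <- paste0(substr(s, 1L, cs - 1L),
                    substr(founder_seq, cs, cs + 2L),
                    substr(s, cs + 3L, nchar(s)))
      }
    }
    s
  }

  for (g in seq_len(n_groups)) {
    unproductive <- g > n_groups - n_unproductive
    if (g == 1L) {
      gf_seq <- founder_seq
      gf_parent <- NA_character_
      gf_gen <- 0L
      target <- founder_cdr3_chars
    } else {
      parent_g <- if (group_parent == "founder") 1L else sample.int(g - 1L, 1L)
      parent_seq <- nodes[[match(group_founder_id[parent_g],
                                 vapply(nodes, `[[`, character(1), "node_id"))]]$sequence
      repeat {
        k <- sample(seq.int(1L, min(3L, length(free_aa))), 1L)
        at <- sample(free_aa, k)
        target <- founder_cdr3_chars
        for (p in at) {
          target[p] <- sample(setdiff(names(AA_CODON), founder_cdr3_chars[p]), 1L)
        }
        cand <- paste(c(target, founder_cdr3_chars[-seq_len(n_insert_aa)]), collapse = "")
        if (!cand %in% group_cdr3[seq_len(g - 1L)]) break
      }
      gf_seq <- engineer_cdr3(parent_seq, target)
      ## branch mutations give the genealogy distinct branch lengths
      nb <- sample(seq.int(branch_mutation_range[1], branch_mutation_range[2]), 1L)
      res <- draw_mutations_exact(gf_seq, nb, pool, w_pool, rmap,
                                  fr_replacement_veto, cdr_silent_veto)
      gf_seq <- res$sequence
      gf_parent <- group_founder_id[parent_g]
      gf_gen <- nodes[[match(gf_parent,
                             vapply(nodes, `[[`, character(1), "node_id"))]]$generation + 1L
    }
    if (unproductive) {
      gf_seq <- paste0(substr(gf_seq, 1L, stop_codon_start - 1L), "TAA",
                       substr(gf_seq, stop_codon_start + 3L, nchar(gf_seq)))
    }
    if (gf_seq %in% seen) stop("duplicate node sequence generated")  # nocov
    seen <- c(seen, gf_seq)
    id <- next_id()
    group_founder_id[g] <- id
    group_cdr3[g] <- cdr3_aa_of(gf_seq, jl)
    parent_for_diff <- if (g == 1L) naive else
      nodes[[match(gf_parent, vapply(nodes, `[[`, character(1), "node_id"))]]$sequence
    add_node(id, gf_parent, gf_gen, gf_seq, parent_for_diff,
             group = g, productive = !unproductive)

    for (m in seq_len(group_sizes[g] - 1L)) {
      repeat {
        nm <- sample(seq.int(member_mutation_range[1], member_mutation_range[2]), 1L)
        res <- draw_mutations_exact(gf_seq, nm, pool, w_pool, rmap,
                                    fr_replacement_veto, cdr_silent_veto)
        if (!res$sequence %in% seen) break
      }
      seen <- c(seen, res$sequence)
      add_node(next_id(), group_founder_id[g],
               nodes[[match(group_founder_id[g],
                            vapply(nodes, `[[`, character(1), "node_id"))]]$generation + 1L,
               res$sequence, gf_seq, group = g, productive = !unproductive)
    }
  }

  lin <- tibble::tibble(
    node_id = vapply(nodes, `[[`, character(1), "node_id"),
    parent_id = vapply(nodes, `[[`, character(1), "parent_id"),
    generation = vapply(nodes, `[[`, integer(1), "generation"),
    sequence = vapply(nodes, `[[`, character(1), "sequence"),
    mutations = lapply(nodes, `[[`, "mutations"),
    cdr3_aa = cdr3_aa_of(vapply(nodes, `[[`, character(1), "sequence"), jl),
    group_id = sprintf("T%02d", vapply(nodes, `[[`, integer(1), "group")),
    productive = vapply(nodes, `[[`, logical(1), "productive"),
    n_from_founder = hamming(vapply(nodes, `[[`, character(1), "sequence"), founder_seq)
  )
  groups_truth <- dplyr::summarise(
    dplyr::group_by(lin, .data$group_id, .data$cdr3_aa, .data$productive),
    n_members = dplyr::n(), .groups = "drop")
  out <- as_clone_lineage(lin, naive = naive, founder = founder, junction_length = jl)
  attr(out, "groups_truth") <- dplyr::arrange(groups_truth, .data$group_id)
  attr(out, "founder_sequence") <- founder_seq
  out
}
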