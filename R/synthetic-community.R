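# Synthetic community generator: reference operon sets derived from a common
# ancestor, lognormal community profiles, two-end-member mixtures, and
# error-prone long amplicon reads with a known truth table.

BASES <- c("A", "C", "G", "T")

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param seq a single DNA string.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) cpp_revcomp(toupper(seq))

# Deterministically instantiate IUPAC codes to the alphabetically first
# compatible base, so generated references are plain A/C/G/T.
instantiate_iupac <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) IUPAC_EXPANSION[[c]][1], ""), collapse = "")
}

#' Describe the architecture of the simulated rRNA operon amplicon
#'
#' The amplicon spans the 16S gene, the intergenic spacer (ITS) and the
#' amplified portion of the 23S gene -- 4200 bp total under the defaults
#' (1500 + 300 + 2400). The terminal priming sites are the 3' segments of
#' the 27F forward and 2241R reverse primers; `anchor_offsets_*` place
#' conserved internal windows that emulate the universal internal primer
#' panel used for read QC (offsets within the respective subunit, 0-based).
#'
#' @param len_16s,len_its,len_23s subunit lengths in bp.
#' @param forward_primer,reverse_primer terminal primer sequences (IUPAC
#'   codes allowed).
#' @param anchor_offsets_16s,anchor_offsets_23s conserved-window offsets.
#' @param anchor_len conserved window length in bp.
#' @return an `operon_model` object.
#' @export
operon_model <- function(len_16s = 1500, len_its = 300, len_23s = 2400,
                         forward_primer = "AGAGTTTGATCCTGGCTCAG",
                         reverse_primer = "ACCGCCCCAGTHAAACT",
                         anchor_offsets_16s = c(343, 518, 907, 1392),
                         anchor_offsets_23s = c(129, 473, 820, 1623),
                         anchor_len = 20) {
  stopifnot(len_16s > 0, len_its > 0, len_23s > 0, anchor_len >= 10)
  chk <- function(p) all(strsplit(toupper(p), "")[[1]] %in% names(IUPAC_EXPANSION))
  if (!chk(forward_primer) || !chk(reverse_primer))
    stop("primers must be valid IUPAC DNA")
  if (any(anchor_offsets_16s + anchor_len > len_16s) || any(anchor_offsets_16s < 0))
    stop("16S anchor windows must lie inside the 16S subunit")
  if (any(anchor_offsets_23s + anchor_len > len_23s) || any(anchor_offsets_23s < 0))
    stop("23S anchor windows must lie inside the 23S subunit")
  structure(list(len_16s = len_16s, len_its = len_its, len_23s = len_23s,
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer),
                 anchor_offsets_16s = anchor_offsets_16s,
                 anchor_offsets_23s = anchor_offsets_23s,
                 anchor_len = anchor_len),
            class = "operon_model")
}

#' @export
print.operon_model <- function(x, ...) {
  cat("rRNA operon amplicon model: 16S ", x$len_16s, " bp + ITS ", x$len_its,
      " bp + 23S ", x$len_23s, " bp = ", x$len_16s + x$len_its + x$len_23s,
      " bp\n", sep = "")
  invisible(x)
}

#' Total amplicon length of an operon model
#' @param model an [operon_model].
#' @return total length in bp.
#' @export
operon_length <- function(model) model$len_16s + model$len_its + model$len_23s

# 0-based half-open intervals of sites kept invariant across taxa: terminal
# priming sites and the internal conserved windows.
conserved_intervals <- function(model) {
  L <- operon_length(model)
  fp <- nchar(model$forward_primer); rp <- nchar(model$reverse_primer)
  ivs <- rbind(c(0, fp), c(L - rp, L))
  for (a in model$anchor_offsets_16s)
    ivs <- rbind(ivs, c(a, a + model$anchor_len))
  for (a in model$anchor_offsets_23s) {
    s <- model$len_16s + model$len_its + a
    ivs <- rbind(ivs, c(s, s + model$anchor_len))
  }
  ivs
}

#' Generate a synthetic rRNA operon reference set
#'
#' Draws a uniform-random ancestor operon, stamps in the terminal priming
#' sites and conserved internal windows, and derives each taxon by
#' substituting every non-conserved site independently with probability
#' `divergence`. The extracted 16S of each taxon is the first `len_16s`
#' bases of its operon.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param divergence expected per-site substitution fraction from the
#'   ancestor, in [0, 0.3]; larger values would push expected identity to the
#'   ancestor below the classifier's 70 percent design floor.
#' @param model an [operon_model].
#' @param seed integer seed.
#' @return a `reference_set` with operon and 16S [seq_records], the ancestor,
#'   and the primer/anchor panel for QC.
#' @export
generate_reference_set <- function(n_taxa, divergence = 0.15,
                                   model = operon_model(), seed) {
  stopifnot(n_taxa >= 1)
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must be in [0, 0.3]: expected identity to the ancestor ",
         "would fall below the classifier's 70% floor")
  rp_set_active_seed(seed)
  set.seed(seed)
  L <- operon_length(model)
  anc <- sample(BASES, L, replace = TRUE)
  # stamp terminal priming sites (IUPAC instantiated) and leave anchors random
  fp <- strsplit(instantiate_iupac(model$forward_primer), "")[[1]]
  rp <- strsplit(instantiate_iupac(revcomp(model$reverse_primer)), "")[[1]]
  anc[seq_along(fp)] <- fp
  anc[(L - length(rp) + 1):L] <- rp
  cons <- rep(FALSE, L)
  ivs <- conserved_intervals(model)
  for (r in seq_len(nrow(ivs))) cons[(ivs[r, 1] + 1):ivs[r, 2]] <- TRUE
  free <- which(!cons)
  ids <- sprintf("taxon_%03d", seq_len(n_taxa))
  ops <- character(n_taxa)
  for (t in seq_len(n_taxa)) {
    x <- anc
    mut <- free[runif(length(free)) < divergence]
    if (length(mut)) {
      # substitute to a uniformly chosen different base
      shift <- sample.int(3, length(mut), replace = TRUE)
      cur <- match(x[mut], BASES)
      x[mut] <- BASES[((cur - 1 + shift) %% 4) + 1]
    }
    ops[t] <- paste(x, collapse = "")
  }
  operons <- seq_records(ids, ops, desc = sprintf("operon divergence=%g", divergence))
  sixteen <- seq_records(ids, substr(ops, 1, model$len_16s), desc = "16S")
  structure(list(taxon_ids = ids, operons = operons, sixteen_s = sixteen,
                 ancestor = paste(anc, collapse = ""), divergence = divergence,
                 model = model, seed = seed,
                 panel = primer_panel_for(model, paste(anc, collapse = ""))),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$taxon_ids), "taxa,",
      operon_length(x$model), "bp operons, divergence", x$divergence, "\n")
  invisible(x)
}

# Panel of priming sites for QC: the two terminal primers plus the conserved
# internal windows read off the ancestor. Names carry the subunit so that
# 16S/23S extraction can tell the sub-panels apart; internal windows are
# named after their offset, echoing conventional primer nomenclature.
primer_panel_for <- function(model, ancestor) {
  ids <- c("16S_27F",
           sprintf("16S_%dF", model$anchor_offsets_16s),
           sprintf("23S_%dF", model$anchor_offsets_23s),
           "23S_2241R")
  seqs <- c(model$forward_primer,
            substring(ancestor, model$anchor_offsets_16s + 1,
                      model$anchor_offsets_16s + model$anchor_len),
            substring(ancestor,
                      model$len_16s + model$len_its + model$anchor_offsets_23s + 1,
                      model$len_16s + model$len_its + model$anchor_offsets_23s +
                        model$anchor_len),
            model$reverse_primer)
  seq_records(ids, seqs, desc = "priming site")
}

#' Draw a skewed community abundance profile
#'
#' Abundances are proportional to exp(N(0, sigma^2)) draws, normalized to
#' sum to one -- the lognormal rank-abundance skew typical of soil and
#' bioreactor communities.
#'
#' @param ref a `reference_set`, or a character vector of taxon ids.
#' @param lognormal_sigma sigma of the underlying normal (0 = uniform).
#' @param seed integer seed.
#' @param taxa optional subset of taxa to include.
#' @return a named `community_profile` vector summing to 1.
#' @export
sample_community <- function(ref, lognormal_sigma = 2, seed, taxa = NULL) {
  stopifnot(lognormal_sigma >= 0)
  ids <- if (is.character(ref)) ref else ref$taxon_ids
  if (!is.null(taxa)) {
    if (!all(taxa %in% ids)) stop("unknown taxa requested")
    ids <- taxa
  }
  set.seed(seed)
  w <- exp(rnorm(length(ids), 0, lognormal_sigma))
  p <- w / sum(w)
  structure(setNames(p, ids), class = "community_profile")
}

#' Mix two community profiles
#'
#' Per-taxon linear combination: `fraction_a * a + (1 - fraction_a) * b`,
#' with absent taxa treated as zero abundance.
#'
#' @param a,b `community_profile` vectors (taxa may differ).
#' @param fraction_a mixing fraction of `a`, in [0, 1].
#' @return a `community_profile` over the union of taxa.
#' @export
mix_profiles <- function(a, b, fraction_a) {
  if (fraction_a < 0 || fraction_a > 1) stop("fraction_a must be in [0, 1]")
  taxa <- union(names(a), names(b))
  av <- setNames(rep(0, length(taxa)), taxa); av[names(a)] <- a
  bv <- setNames(rep(0, length(taxa)), taxa); bv[names(b)] <- b
  p <- fraction_a * av + (1 - fraction_a) * bv
  structure(p, class = "community_profile")
}

#' Per-base sequencing error model
#'
#' Defaults mirror the ~12 percent total error of 2D nanopore reads, split
#' 6/3/3 percent substitution/insertion/deletion.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities.
#' @return an `error_model` object.
#' @export
error_model <- function(sub_rate = 0.06, ins_rate = 0.03, del_rate = 0.03) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("error rates must be in [0, 1) and sum to < 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

# Apply the error model to one sequence (character scalar); returns the
# mutated string and the realized error counts. Uses the current RNG stream.
mutate_sequence <- function(seq, em) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  u <- runif(n)
  is_sub <- u < em$sub_rate
  is_del <- !is_sub & u < em$sub_rate + em$del_rate
  if (any(is_sub)) {
    shift <- sample.int(3, sum(is_sub), replace = TRUE)
    cur <- match(x[is_sub], BASES)
    cur[is.na(cur)] <- 1
    x[is_sub] <- BASES[((cur - 1 + shift) %% 4) + 1]
  }
  ins_here <- runif(n) < em$ins_rate
  n_ins <- sum(ins_here)
  if (n_ins > 0) {
    ins_base <- sample(BASES, n_ins, replace = TRUE)
    pieces <- x
    pieces[ins_here] <- paste0(x[ins_here], ins_base)
    x <- pieces
  }
  keep <- !is_del
  list(seq = paste(x[keep], collapse = ""),
       n_sub = sum(is_sub & keep), n_ins = sum(ins_here & keep),
       n_del = sum(is_del))
}

#' Simulate error-prone 2D amplicon reads from a community
#'
#' Each non-junk read picks a source taxon from the profile, copies its full
#' operon amplicon, applies per-base substitutions/insertions/deletions, and
#' is reverse-complemented with probability 0.5. Junk reads (off-target
#' products outside the 4-5 kb window) are uniform-random fragments of
#' length U(500, 3500) or U(5200, 8000).
#'
#' @param profile a `community_profile` over taxa of `ref`.
#' @param ref a `reference_set`.
#' @param n_reads number of reads (>= 1).
#' @param errors an [error_model].
#' @param seed integer seed.
#' @param junk_fraction fraction of junk reads.
#' @param read_prefix prefix for read ids.
#' @return list with `reads` ([seq_records]) and `truth` (data.frame:
#'   read_id, taxon_id, orientation, n_sub, n_ins, n_del, is_junk).
#' @export
simulate_reads <- function(profile, ref, n_reads, errors = error_model(),
                           seed, junk_fraction = 0.05, read_prefix = "read") {
  stopifnot(n_reads >= 1)
  if (!all(names(profile) %in% ref$taxon_ids))
    stop("profile contains taxa absent from the reference set")
  rp_set_active_seed(seed)
  set.seed(seed)
  operons <- setNames(ref$operons$seq, ref$operons$id)
  is_junk <- runif(n_reads) < junk_fraction
  src <- rep(NA_character_, n_reads)
  n_real <- sum(!is_junk)
  if (n_real > 0)
    src[!is_junk] <- sample(names(profile), n_real, replace = TRUE,
                            prob = as.numeric(profile))
  ids <- sprintf("%s_%05d", read_prefix, seq_len(n_reads))
  seqs <- character(n_reads)
  orient <- character(n_reads)
  nsub <- nins <- ndel <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    if (is_junk[i]) {
      len <- if (runif(1) < 0.5) round(runif(1, 500, 3500))
             else round(runif(1, 5200, 8000))
      seqs[i] <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      orient[i] <- "+"
    } else {
      m <- mutate_sequence(operons[[src[i]]], errors)
      fw <- runif(1) < 0.5
      seqs[i] <- if (fw) m$seq else revcomp(m$seq)
      orient[i] <- if (fw) "+" else "-"
      nsub[i] <- m$n_sub; nins[i] <- m$n_ins; ndel[i] <- m$n_del
    }
  }
  truth <- data.frame(read_id = ids, taxon_id = src, orientation = orient,
                      n_sub = nsub, n_ins = nins, n_del = ndel,
                      is_junk = is_junk, stringsAsFactors = FALSE)
  list(reads = seq_records(ids, seqs, desc = ifelse(is_junk, "junk", src)),
       truth = truth)
}

#' Inject errors into a sequence until a target alignment identity
#'
#' Substitutions and indels (2:1:1 sub:ins:del) are applied uniformly along
#' the sequence, one at a time after an initial conservative batch, until the
#' global alignment identity to the original (matches / alignment columns,
#' gap columns included) first reaches the target or below.
#'
#' @param seq the original sequence (single string).
#' @param target_identity target percent identity, in [70, 100].
#' @param seed integer seed.
#' @return list with `seq` (mutated) and `realized_identity` (percent).
#' @export
inject_errors_to_identity <- function(seq, target_identity, seed) {
  if (target_identity < 70 || target_identity > 100)
    stop("target_identity must be in [70, 100]")
  set.seed(seed)
  if (target_identity >= 100)
    return(list(seq = seq, realized_identity = 100))
  orig <- seq
  L <- nchar(seq)
  identity <- function(s) cpp_align_global(s, orig, 2L, -3L, 5L, 2L, -1L)$identity
  apply_one <- function(s) {
    n <- nchar(s)
    pos <- sample.int(n, 1)
    type <- sample(c("sub", "sub", "ins", "del"), 1)
    ch <- substr(s, pos, pos)
    if (type == "sub") {
      cur <- match(ch, BASES); if (is.na(cur)) cur <- 1
      nb <- BASES[((cur - 1 + sample.int(3, 1)) %% 4) + 1]
      paste0(substr(s, 1, pos - 1), nb, substr(s, pos + 1, n))
    } else if (type == "ins") {
      paste0(substr(s, 1, pos), sample(BASES, 1), substr(s, pos + 1, n))
    } else {
      paste0(substr(s, 1, pos - 1), substr(s, pos + 1, n))
    }
  }
  # conservative initial batch: ~70% of the naive error count estimate
  k0 <- max(0, floor(0.7 * L * (100 - target_identity) / 100))
  s <- seq
  for (i in seq_len(k0)) s <- apply_one(s)
  id <- identity(s)
  guard <- 10 * L
  while (id > target_identity && guard > 0) {
    s <- apply_one(s)
    id <- identity(s)
    guard <- guard - 1
  }
  list(seq = s, realized_identity = id)
}
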