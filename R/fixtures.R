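# Synthetic protein corpus with known latent structure.
#
# Sequences are emitted by a hidden-state Markov grammar whose states play
# the role of local structural environments (helix-like, strand-like,
# coil-like, turn/bend, disordered, membrane-helix, ...). Each state has a
# peaked emission distribution over the 20 standard residues built from
# classical residue propensities, and a self-transition probability that
# controls segment length. The generating state path doubles as the
# per-residue label: states map onto DSSP eight-state letters, the
# disordered state is additionally flagged in a separate mask (mirroring
# the convention that disorder is "missing coordinates", not a DSSP state).
# Per-protein labels come from class-specific mixtures over states: each of
# ten localization classes biases the transition targets, and the membrane
# label is defined by the presence of a long membrane-state segment.

#' Hidden states of the synthetic grammar
#'
#' Helix (H), 3-10 helix (G), pi helix (I), strand (E), bridge (B),
#' turn (T), bend (S), coil (C), disordered (D), membrane helix (M).
#' @export
GRAMMAR_STATES <- c("H", "G", "I", "E", "B", "T", "S", "C", "D", "M")

#' The ten subcellular-localization classes
#'
#' Class names follow the DeepLoc convention; the generator's class
#' mixtures and the per-protein predictor's localization head use this
#' fixed order.
#' @export
LOCALIZATION_CLASSES <- c(
  "Nucleus", "Cytoplasm", "Extracellular", "Mitochondrion", "Cell membrane",
  "Endoplasmic reticulum", "Plastid", "Golgi apparatus", "Lysosome/Vacuole",
  "Peroxisome"
)

# state -> preferred residues (weighted up in the emission distribution)
.state_preferences <- list(
  H = c("A", "L", "E", "M", "Q", "K"),
  G = c("G", "N", "A", "D"),
  I = c("A", "I", "L", "M"),
  E = c("V", "I", "F", "Y", "W", "T"),
  B = c("C", "V", "I", "T"),
  T = c("N", "G", "P", "S"),
  S = c("G", "S", "N", "D"),
  C = c("G", "P", "S", "Q", "N", "D"),
  D = c("P", "E", "S", "Q", "K", "G", "A"),
  M = c("L", "I", "V", "F", "A", "W")
)

#' Default hidden-state grammar for synthetic proteins
#'
#' @param preference_weight Emission weight multiplier for a state's
#'   preferred residues relative to the rest (default 6; higher values give
#'   lower within-state entropy, hence a more learnable grammar).
#' @param self_transition Named numeric vector of per-state self-transition
#'   probabilities (segment-length control).
#' @param mixture_contrast Exponent sharpening the class-specific state
#'   mixtures (default 2). Higher values make the ten localization classes
#'   more separable by state composition; 1 leaves the raw propensity
#'   mixtures, which overlap heavily at typical protein lengths.
#' @param length_meanlog,length_sdlog,length_min,length_max Log-normal
#'   protein-length distribution, clipped to \code{[length_min, length_max]}.
#' @param unknown_frac Fraction of proteins whose membrane annotation is
#'   masked to \code{"unknown"}.
#' @param membrane_min_run Minimum run of membrane-state residues that makes
#'   a protein \code{"membrane"}.
#' @return An object of class \code{grammar_spec}.
#' @export
default_grammar <- function(preference_weight = 6,
                            self_transition = c(
                              H = 0.90, G = 0.75, I = 0.60, E = 0.88,
                              B = 0.50, T = 0.75, S = 0.70, C = 0.85,
                              D = 0.92, M = 0.93),
                            mixture_contrast = 2,
                            length_meanlog = log(150), length_sdlog = 0.3,
                            length_min = 30L, length_max = 2000L,
                            unknown_frac = 0.08,
                            membrane_min_run = 15L) {
  std <- aa_alphabet()$standard
  emission <- t(vapply(GRAMMAR_STATES, function(s) {
    w <- rep(1, 20)
    names(w) <- std
    w[.state_preferences[[s]]] <- preference_weight
    w / sum(w)
  }, numeric(20)))
  colnames(emission) <- std

  # class-specific multiplicative tweaks on the base state mixture
  base_mix <- c(H = 0.22, G = 0.04, I = 0.01, E = 0.18, B = 0.03,
                T = 0.12, S = 0.08, C = 0.24, D = 0.06, M = 0.02)
  tweaks <- list(
    "Nucleus" = c(D = 4, C = 1.5, E = 0.4),
    "Cytoplasm" = c(),
    "Extracellular" = c(E = 2.5, B = 2, D = 0.3, H = 0.5),
    "Mitochondrion" = c(H = 2.2, E = 0.4),
    "Cell membrane" = c(M = 10),
    "Endoplasmic reticulum" = c(M = 4, E = 1.8),
    "Plastid" = c(T = 2.5, G = 2.5, H = 1.2),
    "Golgi apparatus" = c(M = 2.5, S = 2.5),
    "Lysosome/Vacuole" = c(E = 1.8, D = 2.5),
    "Peroxisome" = c(G = 3.5, I = 3, T = 1.8)
  )
  class_mix <- t(vapply(LOCALIZATION_CLASSES, function(cl) {
    m <- base_mix
    tw <- tweaks[[cl]]
    if (length(tw) > 0) m[names(tw)] <- m[names(tw)] * tw
    m <- m^mixture_contrast
    m / sum(m)
  }, numeric(length(GRAMMAR_STATES))))
  colnames(class_mix) <- GRAMMAR_STATES

  spec <- structure(
    list(
      states = GRAMMAR_STATES,
      ss8 = c(H = "H", G = "G", I = "I", E = "E", B = "B",
              T = "T", S = "S", C = "C", D = "C", M = "H"),
      disordered_state = "D", membrane_state = "M",
      emission = emission,
      self_transition = self_transition[GRAMMAR_STATES],
      class_names = LOCALIZATION_CLASSES,
      class_mix = class_mix,
      length_meanlog = length_meanlog, length_sdlog = length_sdlog,
      length_min = as.integer(length_min), length_max = as.integer(length_max),
      unknown_frac = unknown_frac,
      membrane_min_run = as.integer(membrane_min_run)
    ),
    class = "grammar_spec"
  )
  validate_grammar(spec)
  spec
}

#' Validate a grammar specification
#'
#' Checks that emission rows are probability distributions, self-transition
#' probabilities lie in (0, 1), class mixtures are row-stochastic, and no
#' two emission rows coincide (positive pairwise KL divergence, so the
#' grammar is identifiable).
#'
#' @param spec A \code{grammar_spec}.
#' @return \code{spec}, invisibly; errors on violation.
#' @export
validate_grammar <- function(spec) {
  stopifnot(inherits(spec, "grammar_spec"))
  if (any(spec$emission < 0)) stop("negative emission probability")
  if (any(abs(rowSums(spec$emission) - 1) > 1e-9)) {
    stop("emission rows must sum to 1")
  }
  if (any(abs(rowSums(spec$class_mix) - 1) > 1e-9)) {
    stop("class mixture rows must sum to 1")
  }
  st <- spec$self_transition
  if (any(!is.finite(st)) || any(st <= 0) || any(st >= 1)) {
    stop("self-transition probabilities must lie strictly inside (0, 1)")
  }
  ns <- nrow(spec$emission)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    p <- spec$emission[i, ]; q <- spec$emission[j, ]
    sup <- p > 0
    kl <- sum(p[sup] * log(p[sup] / q[sup]))  # +Inf when supports differ
    if (is.nan(kl) || kl <= 0) {
      stop("emission rows ", i, " and ", j, " are not distinguishable")
    }
  }
  invisible(spec)
}

#' Generate a synthetic protein corpus with consistent labels
#'
#' Samples \code{n} proteins from the hidden-state grammar. Per-residue
#' labels are the generating state path mapped to DSSP letters (SS8), the
#' standard eight-to-three reduction (SS3), and a disorder mask marking
#' residues emitted by the disordered state. Per-protein labels are the
#' localization class whose mixture generated the protein and the membrane
#' status derived from the longest membrane-state run (masked to
#' \code{"unknown"} for a configurable fraction). Deterministic given
#' \code{(spec, n, seed)}.
#'
#' @param spec A \code{grammar_spec}.
#' @param n Number of proteins (>= 1).
#' @param seed Integer seed.
#' @param id_prefix Prefix for record ids.
#' @return An object of class \code{fixture_set}: list with
#'   \code{records} (a \code{protein_records} data.frame),
#'   \code{ss8}, \code{ss3}, \code{disorder} (character vectors, one string
#'   per record; disorder mask uses "0"/"1"), \code{hidden} (state paths),
#'   \code{localization}, \code{membrane} (character vectors), and
#'   \code{provenance} (spec + seed).
#' @export
generate_corpus <- function(spec = default_grammar(), n, seed,
                            id_prefix = "syn") {
  validate_grammar(spec)
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  ns <- length(spec$states)
  std <- colnames(spec$emission)

  cls <- sample(spec$class_names, n, replace = TRUE)
  lens <- pmin(pmax(round(stats::rlnorm(n, spec$length_meanlog,
                                        spec$length_sdlog)),
                    spec$length_min), spec$length_max)

  seqs <- character(n); ss8 <- character(n); hidden <- character(n)
  dis <- character(n); memb <- character(n)
  for (i in seq_len(n)) {
    mix <- spec$class_mix[cls[i], ]
    L <- lens[i]
    path <- integer(L)
    path[1] <- sample.int(ns, 1L, prob = mix)
    if (L > 1L) for (t in 2L:L) {
      s <- path[t - 1L]
      if (stats::runif(1) < spec$self_transition[s]) {
        path[t] <- s
      } else {
        w <- mix; w[s] <- 0
        # a state with no alternatives under this mixture is absorbing
        path[t] <- if (sum(w) > 0) sample.int(ns, 1L, prob = w) else s
      }
    }
    res <- vapply(path, function(s) {
      sample(std, 1L, prob = spec$emission[s, ])
    }, "")
    seqs[i] <- paste(res, collapse = "")
    st <- spec$states[path]
    hidden[i] <- paste(st, collapse = "")
    ss8[i] <- paste(spec$ss8[st], collapse = "")
    dis[i] <- paste(as.integer(st == spec$disordered_state), collapse = "")
    memb[i] <- if (.longest_run(st, spec$membrane_state) >=
                   spec$membrane_min_run) "membrane" else "soluble"
  }
  unknown <- stats::runif(n) < spec$unknown_frac
  memb[unknown] <- "unknown"

  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  fs <- structure(
    list(
      records = protein_records(ids, seqs),
      ss8 = stats::setNames(ss8, ids),
      ss3 = stats::setNames(vapply(ss8, map_dssp8_to_3_string, ""), ids),
      disorder = stats::setNames(dis, ids),
      hidden = stats::setNames(hidden, ids),
      localization = stats::setNames(cls, ids),
      membrane = stats::setNames(memb, ids),
      provenance = list(spec = spec, seed = as.integer(seed), n = n)
    ),
    class = "fixture_set"
  )
  fs
}

.longest_run <- function(x, value) {
  r <- rle(x == value)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Look up the per-protein labels of a generated record
#'
#' Labels are stored provenance from generation time; the membrane status is
#' re-derived from the hidden path (longest membrane-state run vs. the
#' spec threshold) so it can be cross-checked independently.
#'
#' @param fixtures A \code{fixture_set}.
#' @param id Record id from that set.
#' @return List with \code{localization} and \code{membrane}.
#' @export
assign_protein_labels <- function(fixtures, id) {
  stopifnot(inherits(fixtures, "fixture_set"))
  if (!id %in% fixtures$records$id) {
    stop("record '", id, "' was not generated by this fixture set")
  }
  list(localization = unname(fixtures$localization[id]),
       membrane = unname(fixtures$membrane[id]))
}

#' Generate a per-residue 50-feature profile fixture
#'
#' Emulates an alignment-profile feature block without running any
#' alignments: layout is \code{[one-hot 20 | substitution profile 20 |
#' 7 transition features | 3 diversity features]}. The substitution-profile
#' block is row-stochastic and peaked at the true residue, with noise drawn
#' from the generating state's emission distribution (so profile noise is
#' correlated with local structure, as in real alignments). Transition
#' features lie in [0, 1]; diversity features are non-negative.
#' Deterministic given \code{seed}.
#'
#' @param fixtures A \code{fixture_set}.
#' @param id Record id.
#' @param seed Integer seed.
#' @param self_weight Weight of the true residue in the profile block.
#' @return A numeric matrix (length x 50) with scheme attribute
#'   \code{"profile50"}.
#' @export
generate_profile_fixture <- function(fixtures, id, seed, self_weight = 0.55) {
  stopifnot(inherits(fixtures, "fixture_set"))
  if (!id %in% fixtures$records$id) stop("unknown record: ", id)
  set.seed(as.integer(seed) + match(id, fixtures$records$id))
  spec <- fixtures$provenance$spec
  seqc <- strsplit(fixtures$records$sequence[fixtures$records$id == id],
                   "")[[1]]
  path <- strsplit(fixtures$hidden[[id]], "")[[1]]
  L <- length(seqc)
  std <- aa_alphabet()$standard
  oh <- matrix(0, L, 20)
  idx <- match(seqc, std)
  ok <- !is.na(idx)
  oh[cbind(which(ok), idx[ok])] <- 1

  prof <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    emis <- spec$emission[match(path[i], spec$states), ]
    noise <- stats::rgamma(20, shape = 40 * emis + 0.2, rate = 1)
    noise <- noise / sum(noise)
    row <- (1 - self_weight) * noise
    if (ok[i]) row[idx[i]] <- row[idx[i]] + self_weight
    prof[i, ] <- row / sum(row)
  }

  # 7 HMM-transition-like features: smooth functions of segment position,
  # jittered and clipped into [0, 1]
  seg <- .segment_position(path)
  trans <- sapply(1:7, function(k) {
    v <- stats::plogis(seg * (k / 3) - k / 2 + stats::rnorm(L, 0, 0.3))
    pmin(pmax(v, 0), 1)
  })
  # 3 diversity features (Neff-style): non-negative
  div <- matrix(stats::rgamma(L * 3, shape = 4, rate = 2), L, 3)
  m <- cbind(oh, prof, trans, div)
  feature_matrix(m, id = id, scheme = "profile50")
}

.segment_position <- function(path) {
  r <- rle(path)
  unlist(lapply(r$lengths, function(l) seq_len(l) / l))
}

# ---- fixture I/O: FASTA + TSV protein labels + per-residue label text ----

#' Write a fixture set to a directory
#'
#' Emits \code{sequences.fasta}, \code{protein_labels.tsv}
#' (id / localization / membrane) and \code{residue_labels.txt}
#' (per record: a ">id" header then three lines: sequence, SS8, disorder
#' mask of 0/1 characters).
#'
#' @param fixtures A \code{fixture_set}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_fixture_set <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixtures$records, file.path(dir, "sequences.fasta"))
  utils::write.table(
    data.frame(id = fixtures$records$id,
               localization = unname(fixtures$localization),
               membrane = unname(fixtures$membrane)),
    file.path(dir, "protein_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  con <- file(file.path(dir, "residue_labels.txt"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(fixtures$records))) {
    id <- fixtures$records$id[i]
    writeLines(c(paste0(">", id), fixtures$records$sequence[i],
                 fixtures$ss8[[id]], fixtures$disorder[[id]]), con)
  }
  invisible(dir)
}

#' Read per-residue labels written by \code{\link{write_fixture_set}}
#'
#' @param path Path to a \code{residue_labels.txt} file.
#' @return List with named character vectors \code{sequence}, \code{ss8},
#'   \code{ss3}, \code{disorder}.
#' @export
read_residue_labels <- function(path) {
  ln <- readLines(path)
  heads <- grep("^>", ln)
  ids <- sub("^>", "", ln[heads])
  seqs <- ln[heads + 1L]; ss8 <- ln[heads + 2L]; dis <- ln[heads + 3L]
  if (any(nchar(seqs) != nchar(ss8)) || any(nchar(seqs) != nchar(dis))) {
    stop("label lengths do not match sequence lengths")
  }
  list(sequence = stats::setNames(seqs, ids),
       ss8 = stats::setNames(ss8, ids),
       ss3 = stats::setNames(vapply(ss8, map_dssp8_to_3_string, ""), ids),
       disorder = stats::setNames(dis, ids))
}

#' Shuffle the residues within each protein of a record set
#'
#' Destroys the grammar's local structure while preserving per-protein
#' composition; used as the null corpus in language-model comparisons.
#'
#' @param records A \code{protein_records} data.frame.
#' @param seed Integer seed.
#' @return A \code{protein_records} data.frame with shuffled sequences.
#' @export
shuffle_residues <- function(records, seed) {
  set.seed(as.integer(seed))
  sh <- vapply(records$sequence, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  protein_records(records$id, sh)
}
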