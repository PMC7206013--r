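# In-silico protease digestion: explicit-site or residue-class cleavage
# rules, tiling fragment inventories, and peptide masses.
#
# Conventions: 1-based inclusive residue numbering; cleavage is C-terminal
# to the named residue (a fragment ends at the cut site).  This matches
# trypsin-like K/R proteases, where the new N-terminus starts one past the
# basic residue.

# standard amino-acid residue masses (Da); monoisotopic and average
.aa_mono <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.aa_avg <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
             V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
             I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
             K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
             F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mono <- 18.0105646863
.water_avg <- 18.01528

.check_sequence <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty protein sequence")
  res <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(res), names(.aa_mono))
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  seq
}

#' Define a cleavage rule
#'
#' Either an explicit list of residue positions whose C-terminal bond is
#' cut, or a residue class (cut after any residue in the set).
#'
#' @param name rule label, e.g. `"metacaspase"` or `"chymotrypsin"`.
#' @param sites integer residue numbers (1-based) to cut after, or `NULL`.
#' @param residues character vector of one-letter codes to cut after, or
#'   `NULL`.  Exactly one of `sites` / `residues` must be given (an empty
#'   `sites` vector is allowed and leaves the chain uncut).
#' @return object of class `"cleavage_rule"`.
#' @examples
#' cleavage_rule("chymotrypsin", residues = c("F", "Y", "W"))
#' cleavage_rule("self", sites = c(180, 190, 210, 225, 237, 267))
#' @export
cleavage_rule <- function(name, sites = NULL, residues = NULL) {
  if (is.null(sites) == is.null(residues))
    stop("give exactly one of `sites` or `residues`")
  if (!is.null(residues)) {
    residues <- toupper(residues)
    if (length(residues) == 0) stop("residue class must be non-empty")
    bad <- setdiff(residues, names(.aa_mono))
    if (length(bad)) stop("unknown residue class members: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(name = name,
                 sites = if (!is.null(sites)) as.integer(sort(sites)),
                 residues = residues),
            class = "cleavage_rule")
}

.cut_positions <- function(seq, rule) {
  n <- nchar(seq)
  if (!is.null(rule$sites)) {
    if (length(rule$sites) && (min(rule$sites) < 1 || max(rule$sites) > n))
      stop("cleavage site outside sequence (length ", n, ")")
    sites <- rule$sites
  } else {
    res <- strsplit(seq, "")[[1]]
    sites <- which(res %in% rule$residues)
  }
  sort(unique(sites[sites < n | sites == n]))  # cut at n produces no tail
}

#' Digest a protein sequence
#'
#' Cuts C-terminal to every position the rule selects and returns the
#' ordered fragment inventory.  Fragments tile the parent exactly; an
#' empty rule returns the parent as a single fragment.  With
#' `n_missed > 0`, peptides spanning up to `n_missed` skipped cut sites
#' are additionally reported in the `"variants"` attribute (the primary
#' set keeps its tiling property).
#'
#' @param seq one-letter protein sequence (character scalar).
#' @param rule a [cleavage_rule()].
#' @param n_missed number of missed cleavages for the variant list
#'   (default 0).
#' @return data.frame of class `"fragment_set"`: `start`, `end` (1-based
#'   inclusive), `length`, `sequence`, `mass_avg`, `mass_mono`.
#' @examples
#' digest("AFGYW", cleavage_rule("chymotrypsin",
#'                               residues = c("F", "Y", "W")))
#' @export
digest <- function(seq, rule, n_missed = 0) {
  seq <- .check_sequence(seq)
  n <- nchar(seq)
  cuts <- .cut_positions(seq, rule)
  bounds <- unique(c(0L, cuts[cuts < n], n))
  starts <- utils::head(bounds, -1) + 1L
  ends <- bounds[-1]
  frag <- .fragment_frame(seq, starts, ends)
  if (n_missed > 0) {
    vstarts <- integer(0); vends <- integer(0)
    for (m in seq_len(n_missed)) {
      i <- seq_len(max(length(starts) - m, 0))
      vstarts <- c(vstarts, starts[i])
      vends <- c(vends, ends[i + m])
    }
    attr(frag, "variants") <- .fragment_frame(seq, vstarts, vends)
  }
  structure(frag, class = c("fragment_set", "data.frame"))
}

.fragment_frame <- function(seq, starts, ends) {
  sequence <- substring(seq, starts, ends)
  masses <- fragment_mass(sequence)
  data.frame(start = starts, end = ends, length = ends - starts + 1L,
             sequence = sequence, mass_avg = masses$average,
             mass_mono = masses$monoisotopic)
}

#' Peptide masses
#'
#' Sum of standard residue masses plus one water, for the average and
#' monoisotopic scales.
#'
#' @param sequence character vector of one-letter peptide sequences.
#' @return data.frame `(average, monoisotopic)` in Da, one row per input.
#' @export
fragment_mass <- function(sequence) {
  out <- t(vapply(sequence, function(s) {
    res <- strsplit(.check_sequence(s), "")[[1]]
    c(sum(.aa_avg[res]) + .water_avg, sum(.aa_mono[res]) + .water_mono)
  }, numeric(2)))
  data.frame(average = out[, 1], monoisotopic = out[, 2],
             row.names = NULL)
}

#' Calcium-dependent substrate-precursor processing products
#'
#' Models the two-regime processing of the 92-residue elicitor precursor:
#' at low (sub-millimolar) calcium the protease cuts only after Arg69,
#' releasing the C-terminal elicitor peptide; at high calcium an
#' additional N-terminal cut after Arg6 and/or Arg7 appears.  A cut is
#' applied only when the residue at the named position is K or R, so an
#' R6A/R7A mutant keeps only the Arg69 cut even at high calcium.
#'
#' @param seq precursor sequence in its own 1-based numbering.
#' @param calcium_level `"low"` or `"high"`.
#' @param primary_site elicitor-release site (default 69).
#' @param high_sites candidate N-terminal sites applied at high calcium
#'   (default 7; use `c(6, 7)` or `6` to model the alternatives).
#' @return a [digest()] fragment set.
#' @examples
#' s <- synthetic_propep1_sequence()
#' propep1_products(s, "low")$end     # 69, 92
#' @export
propep1_products <- function(seq, calcium_level = c("low", "high"),
                             primary_site = 69, high_sites = 7) {
  calcium_level <- match.arg(calcium_level)
  seq <- .check_sequence(seq)
  cand <- if (calcium_level == "low") primary_site else
    sort(c(primary_site, high_sites))
  res <- strsplit(seq, "")[[1]]
  cand <- cand[res[cand] %in% c("K", "R")]
  digest(seq, cleavage_rule("metacaspase-KR", sites = cand))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  out <- toupper(unlist(seqs))
  names(out) <- names(seqs)
  out
}

#' Write a fragment inventory as CSV
#'
#' @param fragments a [digest()] result.
#' @param path output CSV (start, end, length, sequence, masses) for
#'   gel-ladder comparison.
#' @return `path`, invisibly.
#' @export
write_fragments_csv <- function(fragments, path) {
  utils::write.csv(as.data.frame(fragments), path, row.names = FALSE)
  invisible(path)
}

#' Synthetic stand-in sequences
#'
#' The real sequences of the 418-residue metacaspase and its 92-residue
#' substrate precursor are not reproduced here; these deterministic
#' SYNTHETIC stand-ins have the documented residue classes at every named
#' position (His86, Cys139 and the K/R self-cleavage sites 180, 190, 210,
#' 225, 237, 267 for the protease; Arg6, Arg7, Arg69 for the precursor)
#' and no stray K/R elsewhere, so site-specific digestion behaviour is
#' fully determined.
#'
#' @param mutate named integer-to-character replacements applied after
#'   construction, e.g. `c("6" = "A", "7" = "A")` for an R6A/R7A mutant.
#' @return character scalar sequence.
#' @export
synthetic_atmc4_sequence <- function(mutate = NULL) {
  .synthetic_seq(418, anchors = c("86" = "H", "139" = "C", "180" = "R",
                                  "190" = "R", "210" = "K", "225" = "K",
                                  "237" = "K", "267" = "K"),
                 mutate = mutate)
}

#' @rdname synthetic_atmc4_sequence
#' @export
synthetic_propep1_sequence <- function(mutate = NULL) {
  .synthetic_seq(92, anchors = c("6" = "R", "7" = "R", "69" = "R"),
                 mutate = mutate)
}

.synthetic_seq <- function(n, anchors, mutate = NULL) {
  # deterministic filler cycling over non-K/R residues
  filler <- c("A", "S", "T", "G", "V", "L", "D", "E", "N", "Q", "P", "F")
  res <- filler[(seq_len(n) - 1) %% length(filler) + 1]
  res[as.integer(names(anchors))] <- anchors
  if (!is.null(mutate))
    res[as.integer(names(mutate))] <- toupper(mutate)
  paste(res, collapse = "")
}
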