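#' Classify a Sanger consensus sequence against a reference CDS
#'
#' The query is aligned to the reference coding sequence with an
#' ends-free pairwise alignment (match +1, mismatch -2, gap open 5, gap
#' extend 1), which soft-clips incidental vector/primer sequence at the
#' read ends. Differences are then classified, in priority order:
#' a soft-clipped query tail beyond `max(35, 20%)` of the query, or an
#' internal query insertion of `transposon_min` bp or more, indicates a
#' truncated alignment at a new junction (transposon class); remaining
#' alignment gaps are indels (frameshift when the net length is not a
#' multiple of 3); substitutions are translated and called nonsense
#' (stop gained), missense, or silent; an identical sequence is `none`.
#' Queries shorter than 50 bp, or aligning with under 50% identity, are
#' `unassigned`.
#'
#' @param query base-called consensus sequence (character or DNAString).
#' @param ref_cds reference CDS; length must be a multiple of 3 and the
#'   sequence must start with a start codon (ATG/GTG/TTG).
#' @param transposon_min smallest insertion treated as a mobile-element /
#'   junction signature rather than an indel (default 50 bp).
#' @return object of class `mutation_call`: list with `type` (one of
#'   none, silent, missense, nonsense, indel, transposon, unassigned),
#'   `nt_pos` (1-based on the CDS), `protein_pos`, `ref_res`, `alt_res`,
#'   `frameshift`, `indel_len`, `note`.
#' @export
align_and_classify <- function(query, ref_cds, transposon_min = 50) {
  query <- toupper(as.character(query))
  ref <- toupper(as.character(ref_cds))
  n <- nchar(ref)
  gs_assert(n %% 3 == 0, "`ref_cds` length must be divisible by 3")
  gs_assert(substr(ref, 1, 3) %in% c("ATG", "GTG", "TTG"),
            "`ref_cds` must start with a start codon")
  call <- function(type, nt_pos = NA, protein_pos = NA, ref_res = NA,
                   alt_res = NA, frameshift = NA, indel_len = NA,
                   note = "") {
    structure(list(type = type, nt_pos = nt_pos, protein_pos = protein_pos,
                   ref_res = ref_res, alt_res = alt_res,
                   frameshift = frameshift, indel_len = indel_len,
                   note = note),
              class = "mutation_call")
  }
  if (nchar(query) < 50)
    return(call("unassigned", note = "query shorter than 50 bp"))

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1)

  qlen <- nchar(query)
  aln_q_width <- Biostrings::width(Biostrings::pattern(aln))
  if (Biostrings::pid(aln) < 50 || aln_q_width < 25)
    return(call("unassigned", note = "alignment identity below 50%"))

  clipped <- qlen - aln_q_width
  if (clipped > max(35, 0.2 * qlen))
    return(call(
      "transposon",
      nt_pos = Biostrings::start(Biostrings::subject(aln)),
      note = sprintf("truncated alignment: %d bp of query unaligned",
                     clipped)))

  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refpos <- Biostrings::start(Biostrings::subject(aln)) - 1L

  ins_runs <- list(); del_runs <- list(); subs <- list()
  run <- NULL
  flush_run <- function() {
    if (!is.null(run)) {
      if (run$kind == "ins") ins_runs[[length(ins_runs) + 1L]] <<- run
      else del_runs[[length(del_runs) + 1L]] <<- run
    }
    run <<- NULL
  }
  for (i in seq_along(qa)) {
    if (sa[i] == "-") {                 # insertion relative to reference
      if (is.null(run) || run$kind != "ins") {
        flush_run(); run <- list(kind = "ins", pos = refpos, len = 0L)
      }
      run$len <- run$len + 1L
    } else {
      refpos <- refpos + 1L
      if (qa[i] == "-") {               # deletion relative to reference
        if (is.null(run) || run$kind != "del") {
          flush_run(); run <- list(kind = "del", pos = refpos, len = 0L)
        }
        run$len <- run$len + 1L
      } else {
        flush_run()
        if (qa[i] != sa[i]) {
          subs[[length(subs) + 1L]] <- list(pos = refpos, ref = sa[i],
                                            alt = qa[i])
        }
      }
    }
  }
  flush_run()

  big_ins <- Filter(function(r) r$len >= transposon_min, ins_runs)
  if (length(big_ins)) {
    r <- big_ins[[1]]
    return(call("transposon", nt_pos = r$pos, indel_len = r$len,
                note = sprintf("%d bp insertion (new junction)", r$len)))
  }
  indels <- c(ins_runs, del_runs)
  if (length(indels)) {
    net <- sum(vapply(ins_runs, `[[`, 0L, "len")) -
      sum(vapply(del_runs, `[[`, 0L, "len"))
    r <- indels[[which.min(vapply(indels, `[[`, 0L, "pos"))]]
    return(call("indel", nt_pos = r$pos,
                protein_pos = ceiling(r$pos / 3),
                frameshift = (net %% 3) != 0, indel_len = r$len))
  }
  if (!length(subs)) return(call("none"))

  # translate each substituted codon
  gc <- Biostrings::GENETIC_CODE
  effects <- lapply(subs, function(s) {
    ci <- ceiling(s$pos / 3)
    codon_ref <- substr(ref, 3 * ci - 2, 3 * ci)
    codon_alt <- codon_ref
    substr(codon_alt, s$pos - (3 * ci - 3), s$pos - (3 * ci - 3)) <- s$alt
    list(pos = s$pos, codon = ci, aa_ref = gc[[codon_ref]],
         aa_alt = gc[[codon_alt]])
  })
  nonsense <- Filter(function(e) e$aa_alt == "*" && e$aa_ref != "*", effects)
  missense <- Filter(function(e) e$aa_alt != e$aa_ref && e$aa_alt != "*",
                     effects)
  if (length(nonsense)) {
    e <- nonsense[[1]]
    return(call("nonsense", nt_pos = e$pos, protein_pos = e$codon,
                ref_res = e$aa_ref, alt_res = "*"))
  }
  if (length(missense)) {
    e <- missense[[1]]
    return(call("missense", nt_pos = e$pos, protein_pos = e$codon,
                ref_res = e$aa_ref, alt_res = e$aa_alt))
  }
  e <- effects[[1]]
  call("silent", nt_pos = e$pos, protein_pos = e$codon,
       ref_res = e$aa_ref, alt_res = e$aa_alt)
}

#' @export
print.mutation_call <- function(x, ...) {
  cat("mutation_call:", x$type,
      if (!is.na(x$nt_pos)) sprintf("at nt %d", x$nt_pos),
      if (!is.na(x$protein_pos) && x$type %in% c("missense", "nonsense"))
        sprintf("(%s%d%s)", x$ref_res, x$protein_pos, x$alt_res),
      "\n")
  invisible(x)
}

#' Tally a set of mutation calls
#'
#' @param calls list of `mutation_call`s (or a character vector of types).
#' @return list with `tally` (named counts over all classes) and
#'   `fraction_mutated` (share of calls that are not `none`).
#' @export
spectrum <- function(calls) {
  types <- if (is.character(calls)) calls
           else vapply(calls, function(x) x$type, character(1))
  levels <- c("none", "silent", "missense", "nonsense", "indel",
              "transposon", "unassigned")
  gs_assert(all(types %in% levels), "unknown mutation type in calls")
  tally <- table(factor(types, levels = levels))
  list(tally = c(tally),
       fraction_mutated = if (length(types)) mean(types != "none") else 0)
}

#' Conservation-bias rank-sum test for mutated positions
#'
#' Wilcoxon rank-sum comparison of the conservation scores at mutated
#' residues against a background of scores, one-sided toward higher
#' conservation of the mutated positions. The default background is the
#' full profile ("all positions", the mutated residues included); an
#' exclusive background (non-mutated positions only) is also available.
#' For small problems (combined sample size at most `exact_limit`) the
#' p-value is computed by exhaustive enumeration of all rank assignments;
#' otherwise a normal approximation with tie correction is used.
#'
#' @param scores per-residue conservation scores (e.g. the 1-9 scale).
#' @param positions 1-based indices of mutated residues (>= 3).
#' @param background `"all"` (default) or `"exclusive"`.
#' @param exact_limit largest combined sample size for exhaustive
#'   enumeration (default 16).
#' @return list with `W` (rank-sum of the mutated group), `p`
#'   (one-sided), `method` (`"exact"` or `"normal"`).
#' @export
conservation_bias_test <- function(scores, positions,
                                   background = c("all", "exclusive"),
                                   exact_limit = 16) {
  background <- match.arg(background)
  gs_assert(is.numeric(scores) && length(scores) >= 1, "empty profile")
  gs_assert(length(positions) >= 3, "need >= 3 mutated positions")
  gs_assert(all(positions >= 1 & positions <= length(scores)),
            "positions outside the profile")
  x <- scores[positions]
  y <- if (background == "all") scores else scores[-positions]
  if (length(unique(c(x, y))) == 1) {
    gs_warn("all conservation scores identical; test degenerate")
    return(list(W = NA_real_, p = 1, method = "degenerate"))
  }
  combined <- c(x, y)
  r <- rank(combined)
  k <- length(x); N <- length(combined)
  W <- sum(r[seq_len(k)])
  if (N <= exact_limit) {
    sets <- utils::combn(N, k)
    Wall <- colSums(matrix(r[sets], nrow = k))
    p <- mean(Wall >= W - 1e-9)
    return(list(W = W, p = p, method = "exact"))
  }
  mu <- k * (N + 1) / 2
  varpop <- mean((r - (N + 1) / 2)^2)
  v <- k * (N - k) / (N - 1) * varpop
  z <- (W - mu) / sqrt(v)
  list(W = W, p = stats::pnorm(z, lower.tail = FALSE), method = "normal")
}
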