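#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment of two protein sequences against a
#' substitution matrix. A gap of length *k* costs
#' `gap_open + k * gap_extend`, the same convention used by
#' `Biostrings::pairwiseAlignment()`, so scores are directly comparable.
#' The dynamic programme is row-vectorised: the horizontal gap state is a
#' running prefix maximum of `H + j * gap_extend`, which removes the inner
#' column loop while computing the exact optimum.
#'
#' @param a,b protein sequences (character strings).
#' @param matrix substitution matrix (named square numeric matrix);
#'   default BLOSUM62.
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @return list with `score` (best local score, 0 if no positive-scoring
#'   alignment) and `identity` (fraction of identical aligned positions of
#'   the best path, 0-1; `NA` when score is 0).
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 10,
                           gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) return(list(score = 0, identity = NA_real_))
  unknown <- setdiff(unique(c(av, bv)), rownames(matrix))
  if (length(unknown))
    graph_error("residue(s) not in substitution matrix: %s",
                paste(unknown, collapse = ", "))
  ai <- match(av, rownames(matrix))
  bi <- match(bv, colnames(matrix))
  jext <- seq_len(m) * gap_extend

  H_prev <- numeric(m + 1L)            # row i-1 of H, 1-based offset
  E_prev <- rep(-Inf, m + 1L)          # vertical gap state of row i-1
  best <- 0
  best_pos <- c(0L, 0L)
  H_rows <- vector("list", n)          # kept for traceback of identity
  for (i in seq_len(n)) {
    sub <- matrix[ai[i], bi]           # substitution scores vs whole of b
    M <- pmax(0, H_prev[1:m] + sub)                    # diagonal
    E <- pmax(H_prev[2:(m + 1L)] - gap_open - gap_extend,
              E_prev[2:(m + 1L)] - gap_extend)         # gap in b (vertical)
    Hne <- pmax(M, E, 0)
    # horizontal gap: F[j] = max_{k<j} Hne[k] - gap_open - (j-k)*gap_extend
    run <- cummax(c(-Inf, Hne[-m] + jext[-m]))
    F <- run - gap_open - jext
    H <- pmax(Hne, F)
    rb <- max(H)
    if (rb > best) { best <- rb; best_pos <- c(i, which.max(H)) }
    H_rows[[i]] <- H
    H_prev <- c(0, H)
    E_prev <- c(-Inf, E)
  }
  if (best <= 0) return(list(score = 0, identity = NA_real_))
  list(score = best,
       identity = sw_identity(av, bv, ai, bi, matrix, gap_open, gap_extend,
                              H_rows, best_pos))
}

# greedy traceback over the stored H matrix to recover one optimal path and
# report its identity fraction; ties resolved diagonal > up > left
sw_identity <- function(av, bv, ai, bi, matrix, gap_open, gap_extend,
                        H_rows, pos) {
  Hat <- function(i, j) if (i < 1 || j < 1) 0 else H_rows[[i]][j]
  i <- pos[1]; j <- pos[2]
  ident <- 0L; aligned <- 0L
  while (i >= 1 && j >= 1 && Hat(i, j) > 0) {
    h <- Hat(i, j)
    diag <- Hat(i - 1, j - 1) + matrix[ai[i], bi[j]]
    if (isTRUE(all.equal(h, diag)) || h == diag) {
      aligned <- aligned + 1L
      if (av[i] == bv[j]) ident <- ident + 1L
      i <- i - 1; j <- j - 1
      next
    }
    # find the gap move that explains h
    moved <- FALSE
    for (k in seq_len(i - 1)) {
      if (Hat(i - k, j) - gap_open - k * gap_extend == h) {
        aligned <- aligned + k; i <- i - k; moved <- TRUE; break
      }
    }
    if (moved) next
    for (k in seq_len(j - 1)) {
      if (Hat(i, j - k) - gap_open - k * gap_extend == h) {
        aligned <- aligned + k; j <- j - k; moved <- TRUE; break
      }
    }
    if (!moved) break  # numerical dead end; stop traceback
  }
  if (aligned == 0L) return(NA_real_)
  ident / aligned
}

.blosum_cache <- new.env(parent = emptyenv())

#' @rdname smith_waterman
#' @export
blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

#' Sequence-similarity mapping
#'
#' Aligns the protein sequence (attribute `AA`) of every concept of
#' `query_class` against those of all `subject_class` concepts with
#' Smith-Waterman local alignment, keeps at most `top_k` subjects per query
#' with score >= `min_score`, and adds `has_similar_sequence` relations
#' carrying `Score` and `Identity` attributes. Self-hits are excluded;
#' queries without a sequence are skipped with a warning. The relation type
#' is symmetric, so reciprocal hits collapse onto one relation.
#'
#' The score threshold plays the role of the usual E-value cut-off for
#' top-hit filtering; raw scores avoid a database-size calibration and keep
#' the operation deterministic for small datasets.
#'
#' @param g a `kg` (mutated).
#' @param query_class,subject_class concept classes to align.
#' @param top_k maximum hits kept per query (default 10).
#' @param min_score minimum alignment score.
#' @param matrix,gap_open,gap_extend see [smith_waterman()].
#' @return number of `has_similar_sequence` relations added.
#' @export
sequence_map <- function(g, query_class = "Protein", subject_class = "Protein",
                         top_k = 10, min_score = 0, matrix = blosum62(),
                         gap_open = 10, gap_extend = 1) {
  stopifnot(inherits(g, "kg"))
  collect <- function(class) {
    ids <- Filter(function(id) g$concepts[[as.character(id)]]$class == class,
                  kg_concept_ids(g))
    seqs <- lapply(ids, function(id) kg_attr(g, id, "AA"))
    list(ids = ids, seqs = seqs)
  }
  q <- collect(query_class)
  s <- collect(subject_class)
  no_seq <- sum(vapply(q$seqs, is.null, logical(1)))
  if (no_seq > 0)
    warning(sprintf("skipped %d %s quer(y/ies) without a sequence attribute",
                    no_seq, query_class))
  keep_s <- !vapply(s$seqs, is.null, logical(1))
  s$ids <- s$ids[keep_s]; s$seqs <- s$seqs[keep_s]
  keep_q <- !vapply(q$seqs, is.null, logical(1))
  q$ids <- q$ids[keep_q]; q$seqs <- q$seqs[keep_q]
  if (length(q$ids) == 0 || length(s$ids) == 0) return(0L)

  cache <- new.env(parent = emptyenv())   # symmetric score cache
  score_of <- function(qi, si) {
    k <- idx_key(min(qi, si), max(qi, si))
    hit <- cache[[k]]
    if (is.null(hit)) {
      hit <- smith_waterman(kg_attr(g, qi, "AA"), kg_attr(g, si, "AA"),
                            matrix, gap_open, gap_extend)
      cache[[k]] <- hit
    }
    hit
  }

  added <- 0L
  for (qi in q$ids) {
    hits <- list()
    for (si in s$ids) {
      if (si == qi) next
      h <- score_of(qi, si)
      if (h$score >= min_score && h$score > 0)
        hits[[length(hits) + 1L]] <- list(subject = si, score = h$score,
                                          identity = h$identity)
    }
    if (length(hits) == 0) next
    ord <- order(-vapply(hits, `[[`, numeric(1), "score"),
                 vapply(hits, `[[`, numeric(1), "subject"))
    hits <- hits[ord][seq_len(min(top_k, length(hits)))]
    for (h in hits) {
      before <- kg_relation_count(g)
      add_relation(g, qi, h$subject, "has_similar_sequence",
                   attributes = list(Score = as.numeric(h$score),
                                     Identity = as.numeric(h$identity)),
                   source = "UC", evidence = "SEQ")
      if (kg_relation_count(g) > before) added <- added + 1L
    }
  }
  added
}
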