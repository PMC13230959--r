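# Independent brute-force oracles used to verify the package's
# algorithmic paths on small inputs. These deliberately share no code
# with the implementation.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Full Smith-Waterman local alignment (match +1, mismatch -1, gap -2)
# returning the number of identical matched positions on the best path.
# O(nm); intended for sequences up to a few hundred bp.
sw_local_matches <- function(a, b) {
  x <- chars(a); y <- chars(b)
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)  # matches along best path into each cell
  best <- 0; best_m <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (x[i] == y[j]) 1 else -1
      sub_m <- M[i, j] + as.integer(x[i] == y[j])
      del <- H[i, j + 1] - 2; del_m <- M[i, j + 1]
      ins <- H[i + 1, j] - 2; ins_m <- M[i + 1, j]
      h <- max(0, sub, del, ins)
      H[i + 1, j + 1] <- h
      M[i + 1, j + 1] <- if (h == 0) 0L else if (h == sub) sub_m else
        if (h == del) del_m else ins_m
      if (h > best) { best <- h; best_m <- M[i + 1, j + 1] }
    }
  }
  list(score = best, matches = best_m)
}

# Exhaustive gapless local alignment: scans every diagonal of the full
# DP lattice and finds the single best-scoring (+1/-1) segment by
# Kadane's algorithm. Returns the identical-position count of that
# segment. Feasible at 1 kb x 1 kb.
best_gapless_local <- function(a, b) {
  x <- chars(a); y <- chars(b)
  n <- length(x); m <- length(y)
  best_score <- -Inf; best_matches <- 0L
  for (d in (-(n - 1)):(m - 1)) {
    i1 <- max(1, 1 - d); i2 <- min(n, m - d)
    if (i2 < i1) next
    mv <- x[i1:i2] == y[(i1:i2) + d]
    sc <- ifelse(mv, 1, -1)
    # Kadane with segment match bookkeeping
    cur <- 0; cur_m <- 0L; loc_best <- -Inf; loc_m <- 0L
    for (k in seq_along(sc)) {
      if (cur <= 0) { cur <- sc[k]; cur_m <- as.integer(mv[k]) }
      else { cur <- cur + sc[k]; cur_m <- cur_m + as.integer(mv[k]) }
      if (cur > loc_best) { loc_best <- cur; loc_m <- cur_m }
    }
    if (loc_best > best_score) { best_score <- loc_best; best_matches <- loc_m }
  }
  list(score = best_score, matches = best_matches)
}

# From-scratch Benjamini-Hochberg step-up adjusted p-values.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Exhaustive mutual-best-hit oracle over a precomputed identity matrix
# (rows = repertoire A, cols = repertoire B). Ties broken
# lexicographically, candidates below the floor dropped.
bbh_oracle <- function(idm, floor = 0.35) {
  idm[idm < floor] <- NA
  pairs <- list()
  for (p in sort(rownames(idm))) {
    row <- idm[p, ]
    if (all(is.na(row))) next
    q <- sort(names(row)[which(row == max(row, na.rm = TRUE))])[1]
    col <- idm[, q]
    pbest <- sort(names(col)[which(col == max(col, na.rm = TRUE))])[1]
    if (pbest == p) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        protein_a = p, protein_b = q, identity = idm[p, q],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) return(data.frame(protein_a = character(),
                                        protein_b = character(),
                                        identity = numeric()))
  do.call(rbind, pairs)
}

# Protein percent identity computed directly with Biostrings, for
# building oracle identity matrices in tests.
test_identity <- function(q, s) {
  aa <- Biostrings::AA_ALPHABET
  sm <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(q),
                                       Biostrings::AAString(s),
                                       type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 2, gapExtension = 1)
  pat <- chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- chars(as.character(Biostrings::alignedSubject(aln)))
  sum(pat == sub & pat != "-") / length(pat)
}

# Independent checker of every primer-design constraint on one candidate
# row, given the retained SNP positions.
check_primer_row <- function(row, pos,
                             primer_len = c(25, 40), amp = c(180, 300),
                             probe_len = c(18, 30), min_specific = 2) {
  flen <- row$fwd_end - row$fwd_start
  rlen <- row$rev_end - row$rev_start
  plen <- row$probe_end - row$probe_start
  nin <- function(s, e) sum(pos >= s & pos < e)
  ok <- flen >= primer_len[1] && flen <= primer_len[2] &&
    rlen >= primer_len[1] && rlen <= primer_len[2] &&
    row$amplicon_length >= amp[1] && row$amplicon_length <= amp[2] &&
    row$amplicon_length == row$rev_end - row$fwd_start &&
    nin(row$fwd_start, row$fwd_end) >= min_specific &&
    nin(row$rev_start, row$rev_end) >= min_specific &&
    plen >= probe_len[1] && plen <= probe_len[2] &&
    row$probe_start >= row$fwd_end && row$probe_end <= row$rev_start &&
    nin(row$probe_start, row$probe_end) >= 1 &&
    row$rev_start >= row$fwd_end
  isTRUE(ok)
}

# Brute-force primer enumeration over ALL (start, length) window pairs
# in [0, ref_len), returning the best candidate under the package's
# ranking (total specific desc, amplicon asc, fwd start, rev start).
primer_oracle_best <- function(pos, ref_len,
                               primer_len = 25:40, amp = c(180, 300),
                               probe_len = 18:30, min_specific = 2) {
  nin <- function(s, e) sum(pos >= s & pos < e)
  wins <- list()
  for (len in primer_len) {
    for (s in 0:(ref_len - len)) {
      k <- nin(s, s + len)
      if (k >= min_specific) wins[[length(wins) + 1L]] <- c(s, s + len, k)
    }
  }
  if (!length(wins)) return(NULL)
  w <- do.call(rbind, wins)
  best <- NULL
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(nrow(w))) {
      fs <- w[i, 1]; fe <- w[i, 2]; rs <- w[j, 1]; re_ <- w[j, 2]
      if (rs < fe) next
      al <- re_ - fs
      if (al < amp[1] || al > amp[2]) next
      # any valid probe window with >= 1 position?
      feasible <- FALSE
      for (plen in probe_len) {
        if (rs - fe < plen) next
        for (ps in fe:(rs - plen)) {
          if (nin(ps, ps + plen) >= 1) { feasible <- TRUE; break }
        }
        if (feasible) break
      }
      if (!feasible) next
      cand <- c(total = w[i, 3] + w[j, 3], amp = al, fs = fs, rs = rs,
                fe = fe, re_ = re_, fk = w[i, 3], rk = w[j, 3])
      if (is.null(best) ||
          cand["total"] > best["total"] ||
          (cand["total"] == best["total"] && cand["amp"] < best["amp"]) ||
          (cand["total"] == best["total"] && cand["amp"] == best["amp"] &&
             cand["fs"] < best["fs"]) ||
          (cand["total"] == best["total"] && cand["amp"] == best["amp"] &&
             cand["fs"] == best["fs"] && cand["rs"] < best["rs"])) {
        best <- cand
      }
    }
  }
  best
}
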