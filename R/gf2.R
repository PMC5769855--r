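# Sparse GF(2) column algebra. A column is a strictly increasing integer
# vector of row indices; the zero column is integer(0). Entries never repeat,
# so symmetric difference implements addition over Z2.

gf2_xor <- function(a, b) {
  v <- sort.int(c(a, b), method = "radix")
  r <- rle(v)
  r$values[r$lengths == 1L]
}

# Rank of a column set by left-to-right elimination on lowest-one pivots.
gf2_rank <- function(cols, n_rows) {
  if (!length(cols)) return(0L)
  pivot <- vector("list", n_rows)
  rank <- 0L
  for (col in cols) {
    while (length(col)) {
      l <- col[length(col)]
      p <- pivot[[l]]
      if (is.null(p)) {
        pivot[[l]] <- col
        rank <- rank + 1L
        break
      }
      col <- gf2_xor(col, p)
    }
  }
  rank
}

# Is b in the column span of cols?
gf2_in_span <- function(cols, b, n_rows) {
  pivot <- vector("list", n_rows)
  for (col in cols) {
    while (length(col)) {
      l <- col[length(col)]
      p <- pivot[[l]]
      if (is.null(p)) {
        pivot[[l]] <- col
        break
      }
      col <- gf2_xor(col, p)
    }
  }
  while (length(b)) {
    p <- pivot[[b[length(b)]]]
    if (is.null(p)) return(FALSE)
    b <- gf2_xor(b, p)
  }
  TRUE
}

# Null-space basis of the matrix with the given columns, as a list of
# combination vectors (column indices whose GF(2) sum is zero).
gf2_nullspace <- function(cols, n_rows) {
  pivot_col <- vector("list", n_rows)   # reduced column rows
  pivot_combo <- vector("list", n_rows) # which original columns it sums
  basis <- list()
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    combo <- j
    while (length(col)) {
      l <- col[length(col)]
      p <- pivot_col[[l]]
      if (is.null(p)) break
      col <- gf2_xor(col, p)
      combo <- gf2_xor(combo, pivot_combo[[l]])
    }
    if (length(col)) {
      l <- col[length(col)]
      pivot_col[[l]] <- col
      pivot_combo[[l]] <- combo
    } else {
      basis[[length(basis) + 1L]] <- combo
    }
  }
  basis
}
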