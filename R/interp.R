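## Vectorized interpolation kernels shared by the renderer and dosimetry.

# Bilinear sample of matrix m at continuous (row, col) positions (1-based).
# Samples outside the grid return `fill`; the far boundary is inclusive.
.bilinear <- function(m, row, col, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;  fc <- col - c0
  hit <- r0 == nr & fr == 0; r0[hit] <- nr - 1L; fr[hit] <- 1
  hit <- c0 == nc & fc == 0; c0[hit] <- nc - 1L; fc[hit] <- 1
  ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  ok[is.na(ok)] <- FALSE
  out <- rep(fill, length(row))
  if (!any(ok)) return(out)
  r0 <- r0[ok]; c0 <- c0[ok]; fr <- fr[ok]; fc <- fc[ok]
  out[ok] <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
             fr * (1 - fc)       * m[cbind(r0 + 1L, c0)] +
             (1 - fr) * fc       * m[cbind(r0, c0 + 1L)] +
             fr * fc             * m[cbind(r0 + 1L, c0 + 1L)]
  out
}

# Translate a matrix by (dRow, dCol) pixels (possibly fractional); content
# moves by +dRow/+dCol, i.e. out[r, c] = m[r - dRow, c - dCol]; fill outside.
.shiftImage <- function(m, dRow, dCol, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- rep(seq_len(nr), nc) - dRow
  cols <- rep(seq_len(nc), each = nr) - dCol
  matrix(.bilinear(m, rows, cols, fill = fill), nr, nc)
}

# Trilinear sample of 3D array a at continuous voxel coordinates (1-based).
.trilinear <- function(a, i, j, k, fill = 0) {
  d <- dim(a)
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  hit <- i0 == d[1] & fi == 0; i0[hit] <- d[1] - 1L; fi[hit] <- 1
  hit <- j0 == d[2] & fj == 0; j0[hit] <- d[2] - 1L; fj[hit] <- 1
  hit <- k0 == d[3] & fk == 0; k0[hit] <- d[3] - 1L; fk[hit] <- 1
  ok <- i0 >= 1 & i0 + 1 <= d[1] & j0 >= 1 & j0 + 1 <= d[2] &
        k0 >= 1 & k0 + 1 <= d[3]
  ok[is.na(ok)] <- FALSE
  out <- rep(fill, length(i))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  idx <- function(ii, jj, kk) ii + d[1] * ((jj - 1L) + d[2] * (kk - 1L))
  v000 <- a[idx(i0, j0, k0)];         v100 <- a[idx(i0 + 1L, j0, k0)]
  v010 <- a[idx(i0, j0 + 1L, k0)];    v110 <- a[idx(i0 + 1L, j0 + 1L, k0)]
  v001 <- a[idx(i0, j0, k0 + 1L)];    v101 <- a[idx(i0 + 1L, j0, k0 + 1L)]
  v011 <- a[idx(i0, j0 + 1L, k0 + 1L)]
  v111 <- a[idx(i0 + 1L, j0 + 1L, k0 + 1L)]
  c00 <- v000 * (1 - fi) + v100 * fi
  c10 <- v010 * (1 - fi) + v110 * fi
  c01 <- v001 * (1 - fi) + v101 * fi
  c11 <- v011 * (1 - fi) + v111 * fi
  c0 <- c00 * (1 - fj) + c10 * fj
  c1 <- c01 * (1 - fj) + c11 * fj
  out[ok] <- c0 * (1 - fk) + c1 * fk
  out
}
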