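# Internal fast paths for the Gillespie loop. The exported rate/apply
# functions wrap these cores, so the simulated chain and the documented API
# share one set of event semantics.

# event kind codes used in the hot loop
.KIND <- c("move_to_empty", "move_to_single", "proliferate", "die", "degrade")

.movement_rates_core <- function(grid, u, pvals, params) {
  movers <- which(u == 1L | u == 2L)
  out <- list(i = integer(0), j = integer(0), rate = numeric(0), kind = integer(0))
  if (!length(movers)) return(out)
  sig <- params$sigma > 0
  if (sig) {
    nb <- grid$nbr[movers, , drop = FALSE]
    emptynb <- is.na(nb) | matrix(u[ifelse(is.na(nb), 1L, nb)] == 0L, nrow(nb))
    rim <- logical(grid$n^2)
    rim[movers] <- rowSums(emptynb) > 0
  }
  h2 <- grid$h^2
  acc_i <- vector("list", 12); acc_j <- acc_i; acc_r <- acc_i; acc_k <- acc_i
  na <- 0L
  for (d in 1:4) {
    j <- grid$nbr[movers, d]
    ok <- !is.na(j)
    i0 <- movers[ok]; j0 <- j[ok]
    flux <- pvals[i0] - pvals[j0]
    pos <- !is.na(flux) & flux > 0
    sel <- pos & u[j0] == 0L
    if (any(sel)) {
      na <- na + 1L
      acc_i[[na]] <- i0[sel]; acc_j[[na]] <- j0[sel]
      acc_r[[na]] <- params$D1 * flux[sel] / h2
      acc_k[[na]] <- rep.int(1L, sum(sel))
    }
    sel <- pos & u[i0] == 2L & u[j0] == 1L
    if (any(sel)) {
      na <- na + 1L
      acc_i[[na]] <- i0[sel]; acc_j[[na]] <- j0[sel]
      acc_r[[na]] <- params$D2 * flux[sel] / h2
      acc_k[[na]] <- rep.int(2L, sum(sel))
    }
    if (sig) {
      sel <- pos & u[i0] == 1L & u[j0] == 1L & (rim[i0] | rim[j0])
      if (any(sel)) {
        na <- na + 1L
        acc_i[[na]] <- i0[sel]; acc_j[[na]] <- j0[sel]
        acc_r[[na]] <- params$D1 * flux[sel] / h2
        acc_k[[na]] <- rep.int(2L, sum(sel))
      }
    }
  }
  if (na == 0L) return(out)
  list(i = unlist(acc_i[1:na]), j = unlist(acc_j[1:na]),
       rate = unlist(acc_r[1:na]), kind = unlist(acc_k[1:na]))
}

.cell_rates_core <- function(u, cvals, params, channels) {
  i <- integer(0); rate <- numeric(0); kind <- integer(0)
  if ("proliferate" %in% channels) {
    prol <- which(u == 1L & cvals >= params$kappa_prol)
    i <- c(i, prol); rate <- c(rate, rep.int(1, length(prol)))
    kind <- c(kind, rep.int(3L, length(prol)))
  }
  if ("die" %in% channels && params$mu_death > 0) {
    dying <- which(u >= 1L & cvals < params$kappa_death)
    i <- c(i, dying); rate <- c(rate, params$mu_death * u[dying])
    kind <- c(kind, rep.int(4L, length(dying)))
  }
  if ("degrade" %in% channels && params$mu_deg > 0) {
    deg <- which(u == -1L)
    i <- c(i, deg); rate <- c(rate, rep.int(params$mu_deg, length(deg)))
    kind <- c(kind, rep.int(5L, length(deg)))
  }
  list(i = i, j = rep.int(NA_integer_, length(i)), rate = rate, kind = kind)
}

# dense Cholesky solve of the masked Poisson problem for modest tumor sizes;
# falls back to the sparse path above ~600 unknowns
.pressure_core <- function(grid, u, params, bc_fun) {
  active <- which(u != 0L)
  m <- length(active)
  if (!m) stop("empty tumor domain", call. = FALSE)
  h2 <- grid$h^2
  nb <- grid$nbr[active, , drop = FALSE]
  local <- integer(grid$n^2)
  local[active] <- seq_len(m)
  vals <- rep(NA_real_, grid$n^2)
  src <- as.numeric(u[active] > 1L)
  nbsafe <- ifelse(is.na(nb), 1L, nb)
  inA <- !is.na(nb) & matrix(local[nbsafe] > 0L, m)
  rimnb <- !is.na(nb) & !inA                    # on-lattice non-tumor neighbors
  rim_nodes <- unique(nb[rimnb])
  bc <- bc_fun(rim_nodes)
  bcval <- numeric(grid$n^2)
  bcval[rim_nodes] <- bc
  deg <- rowSums(inA | rimnb)
  b <- src * h2 + rowSums(matrix(ifelse(rimnb, bcval[nbsafe], 0), m))
  if (m <= 600L) {
    A <- diag(deg, m)
    for (d in 1:4) {
      sel <- inA[, d]
      if (any(sel)) A[cbind(which(sel), local[nb[sel, d]])] <- -1
    }
    R <- chol(A)
    sol <- backsolve(R, backsolve(R, b, transpose = TRUE))
  } else {
    ii <- rep(seq_len(m), 4)[inA]
    jj <- local[nb[inA]]
    A <- Matrix::sparseMatrix(i = c(seq_len(m), ii), j = c(seq_len(m), jj),
                              x = c(deg, rep(-1, length(ii))), dims = c(m, m))
    sol <- as.numeric(Matrix::solve(A, b))
  }
  vals[active] <- sol
  vals[rim_nodes] <- bcval[rim_nodes]
  list(values = vals, active = active, rim = rim_nodes)
}
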