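# Internal helpers shared across modules.

# Reserved (non-locus) columns of an allele table.
.reserved_cols <- c("sample_id", "role", "patch_id", "cluster_id", "mother_id", "x", "y")

.roles <- c("donor", "receptor", "offspring")

#' Locus names of an allele table
#'
#' Loci are stored as paired integer columns `<locus>_1` / `<locus>_2`
#' (missing allele = 0). The panel is recovered from the column names.
#'
#' @param genotypes An allele table (see [read_allele_table()]).
#' @return Character vector of locus names, in column order.
#' @export
locus_names <- function(genotypes) {
  nm <- setdiff(names(genotypes), .reserved_cols)
  first <- sub("_1$", "", nm[grepl("_1$", nm)])
  second <- sub("_2$", "", nm[grepl("_2$", nm)])
  loci <- intersect(first, second)
  if (length(loci) == 0L) {
    abort("no locus columns found: expected paired columns '<locus>_1'/'<locus>_2'")
  }
  loci
}

# Allele matrix (n x 2) for one locus.
.locus_mat <- function(genotypes, locus) {
  cbind(genotypes[[paste0(locus, "_1")]], genotypes[[paste0(locus, "_2")]])
}

# Derive a named substream seed from a master seed; kept below 2^31.
.sub_seed <- function(seed, stream) {
  offsets <- c(
    landscape = 101L, genets = 211L, routes = 307L, errors = 401L,
    receptors = 503L, runs = 601L, model = 701L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 31L + off) %% 2147483647)
}

# log(sum(exp(x))) guarding -Inf.
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)), Golub-Welsch.
.gh_rule <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- diag(0, n)
  b <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * e$vectors[1L, idx]^2)
}

# Central-difference Hessian of f at x.
.num_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  h <- eps * (1 + abs(x))
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# AICc from logLik, parameter count and sample size.
.aicc <- function(ll, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Zero-truncated negative binomial draws.
.rztnb <- function(n, size, mu, max = Inf) {
  out <- integer(0)
  while (length(out) < n) {
    x <- rnbinom(2L * (n - length(out)) + 10L, size = size, mu = mu)
    x <- x[x > 0 & x <= max]
    out <- c(out, x)
  }
  out[seq_len(n)]
}
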