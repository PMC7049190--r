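# Two-layer block-coordinate optimization of the mixture model.
#
# Inner layer (given fractions): alternate per-gene profile estimation and
# per-sample subtype reassignment. Outer layer: alternate the inner layer
# with per-sample fraction optimization. Profile estimation is a
# box-constrained quasi-Newton fit (L-BFGS-B) with analytic gradients; the
# per-gene problems are separable, so they are solved jointly on the stacked
# parameter vector in one call.

#' Optimizer configuration
#'
#' @param max_inner_iter,max_outer_iter Iteration caps for the inner
#'   (profiles / reassignment) and outer (inner layer / fractions) loops.
#' @param rel_tol_inner,rel_tol_outer Relative objective-change convergence
#'   tolerances for the two loops.
#' @param kmeans_restarts Number of random restarts for the K-means
#'   initialization of subtype labels.
#' @param seed Integer seed driving K-means restarts (and nothing else); all
#'   remaining steps are deterministic.
#' @param profile_bounds_pad Log-units of padding added around the per-gene
#'   observed range to form the box constraints on profile values.
#' @param optim_maxit,optim_factr `maxit` and `factr` passed to
#'   [stats::optim()] (L-BFGS-B) for profile fits.
#' @param grid_optim_maxit Looser `maxit` used during the scaling-constant
#'   grid search, where only relative comparison between grid pairs matters.
#' @param refine_maxit Iteration cap for the joint quasi-Newton refinement
#'   of profiles and fractions that closes each outer iteration.
#' @param min_cancer_fraction Feasibility floor on the cancer fraction used
#'   by the grid search and the fraction optimizer.
#' @return A list of class `declust_config`.
#' @export
declust_control <- function(max_inner_iter = 20L, max_outer_iter = 10L,
                            rel_tol_inner = 1e-6, rel_tol_outer = 1e-5,
                            kmeans_restarts = 25L, seed = 1L,
                            profile_bounds_pad = 2,
                            optim_maxit = 100L, optim_factr = 1e7,
                            grid_optim_maxit = 15L,
                            refine_maxit = 500L,
                            min_cancer_fraction = 0.01) {
  stopifnot(max_inner_iter >= 1L, max_outer_iter >= 1L,
            rel_tol_inner > 0, rel_tol_outer > 0, kmeans_restarts >= 1L,
            profile_bounds_pad >= 0, optim_maxit >= 1L, grid_optim_maxit >= 1L,
            min_cancer_fraction >= 0, min_cancer_fraction < 1)
  structure(
    list(max_inner_iter = as.integer(max_inner_iter),
         max_outer_iter = as.integer(max_outer_iter),
         rel_tol_inner = rel_tol_inner, rel_tol_outer = rel_tol_outer,
         kmeans_restarts = as.integer(kmeans_restarts),
         seed = as.integer(seed),
         profile_bounds_pad = profile_bounds_pad,
         optim_maxit = as.integer(optim_maxit), optim_factr = optim_factr,
         grid_optim_maxit = as.integer(grid_optim_maxit),
         refine_maxit = as.integer(refine_maxit),
         min_cancer_fraction = min_cancer_fraction),
    class = "declust_config"
  )
}

# Joint L-BFGS-B over the stacked per-gene profile parameters.
# warm: genes x (K + 2) matrix of log profiles (K cancer cols, immune, stromal).
# Returns the optimized matrix; guaranteed not to increase the objective.
#' @keywords internal
.optimize_profiles_joint <- function(observed, fractions, assignment, warm,
                                     config, maxit = config$optim_maxit) {
  G <- nrow(observed)
  K <- ncol(warm) - 2L
  fc <- fractions[, "cancer"]; fi <- fractions[, "immune"]; fs <- fractions[, "stromal"]
  idx_by_k <- lapply(seq_len(K), function(k) which(assignment == k))
  rng_lo <- apply(observed, 1L, min) - config$profile_bounds_pad
  rng_hi <- apply(observed, 1L, max) + config$profile_bounds_pad
  lower <- rep(rng_lo, times = K + 2L)
  upper <- rep(rng_hi, times = K + 2L)
  warm <- pmin(pmax(warm, matrix(rng_lo, G, K + 2L)), matrix(rng_hi, G, K + 2L))

  mix <- function(L) {
    M <- L[, assignment, drop = FALSE] * rep(fc, each = G)
    M + tcrossprod(L[, K + 1L], fi) + tcrossprod(L[, K + 2L], fs)
  }
  # optim evaluates fn and gr at the same point; cache the shared mixture
  cache <- new.env(parent = emptyenv())
  eval_point <- function(par) {
    if (!identical(par, cache$par)) {
      L <- exp(matrix(par, G))
      cache$par <- par
      cache$L <- L
      cache$M <- mix(L)
    }
    cache
  }
  fn <- function(par) {
    cc <- eval_point(par)
    R <- observed - log(cc$M)
    sum(R * R)
  }
  gr <- function(par) {
    cc <- eval_point(par)
    L <- cc$L
    M <- cc$M
    W <- -2 * (observed - log(M)) / M
    Tc <- W * rep(fc, each = G)
    gcan <- matrix(0, G, K)
    for (k in seq_len(K)) {
      j <- idx_by_k[[k]]
      if (length(j)) gcan[, k] <- rowSums(Tc[, j, drop = FALSE]) * L[, k]
    }
    gi <- as.vector(W %*% fi) * L[, K + 1L]
    gs <- as.vector(W %*% fs) * L[, K + 2L]
    c(gcan, gi, gs)
  }

  f0 <- fn(as.vector(warm))
  res <- tryCatch(
    stats::optim(as.vector(warm), fn, gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = config$optim_factr)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value) || res$value > f0) {
    out <- warm
    attr(out, "objective") <- f0
    attr(out, "fallback") <- TRUE
    return(out)
  }
  out <- matrix(res$par, G)
  rownames(out) <- rownames(observed)
  attr(out, "objective") <- res$value
  attr(out, "fallback") <- FALSE
  out
}

#' @keywords internal
.profiles_from_matrix <- function(P, gene_ids = NULL) {
  K <- ncol(P) - 2L
  cancer <- P[, seq_len(K), drop = FALSE]
  if (!is.null(gene_ids)) rownames(cancer) <- gene_ids
  colnames(cancer) <- paste0("subtype_", seq_len(K))
  compartment_profiles(cancer, P[, K + 1L], P[, K + 2L])
}

#' @keywords internal
.profiles_to_matrix <- function(profiles) {
  cbind(profiles$cancer, profiles$immune, profiles$stromal)
}

#' Fit the single-subtype model (inner-layer step 0)
#'
#' Assumes one cancer subtype for all samples and estimates, per gene, the
#' cancer, immune, and stromal log profile values minimizing the squared
#' log-reconstruction error given the fractions.
#'
#' @inheritParams compute_mse
#' @param config A [declust_control()] object.
#' @return A `declust_profiles` object with K = 1. If the fractions leave a
#'   compartment without support (e.g. all samples pure cancer), the
#'   unidentifiable profiles stay at their initialization and are flagged in
#'   attribute `"unidentifiable_compartments"`.
#' @export
fit_single_subtype <- function(observed, fractions, config = declust_control()) {
  validate_expression_matrix(observed)
  validate_fractions(fractions)
  if (nrow(fractions) != ncol(observed)) stop("fractions/sample count mismatch")
  mu <- rowMeans(observed)
  warm <- cbind(mu, mu, mu)
  P <- .optimize_profiles_joint(observed, fractions, rep(1L, ncol(observed)),
                                warm, config)
  prof <- .profiles_from_matrix(P, rownames(observed))
  unident <- c("cancer", "immune", "stromal")[colSums(fractions) <= 0]
  attr(prof, "unidentifiable_compartments") <- unident
  prof
}

#' Initial subtype labels from residual clustering
#'
#' K-means over samples (columns of the residual matrix) with multiple
#' restarts under a fixed seed; cluster labels are renumbered by descending
#' cluster size for determinism.
#'
#' @param residuals Genes x samples residual matrix (see
#'   [compute_residuals()]).
#' @param n_subtypes Number of clusters K.
#' @param config A [declust_control()] object (seed, restarts).
#' @return Integer vector of labels in 1..K.
#' @export
init_subtypes <- function(residuals, n_subtypes, config = declust_control()) {
  n <- ncol(residuals)
  if (n_subtypes > n) stop("more subtypes than samples")
  if (n_subtypes == 1L) return(rep(1L, n))
  km <- withr::with_seed(config$seed, {
    stats::kmeans(t(residuals), centers = n_subtypes,
                  nstart = config$kmeans_restarts, iter.max = 50L)
  })
  cl <- km$cluster
  ord <- order(-tabulate(cl, n_subtypes), seq_len(n_subtypes))
  match(cl, ord)
}

#' Optimize compartment profiles given labels and fractions (step 1.1)
#'
#' Per-gene minimization of the squared log-reconstruction error over the K
#' cancer subtype values and the immune and stromal values, warm-started and
#' box-constrained; the separable per-gene problems are solved jointly.
#' Subtypes with no member samples keep their warm-start column (flagged in
#' attribute `"empty_subtypes"`).
#'
#' @inheritParams compute_mse
#' @param warm_start_profiles `declust_profiles` warm start.
#' @param config A [declust_control()] object.
#' @param maxit Optimizer iteration cap (defaults to `config$optim_maxit`).
#' @return A `declust_profiles` object; never worse than the warm start in
#'   objective.
#' @export
optimize_profiles <- function(observed, fractions, assignment,
                              warm_start_profiles, config = declust_control(),
                              maxit = config$optim_maxit) {
  validate_expression_matrix(observed)
  validate_fractions(fractions)
  K <- warm_start_profiles$n_subtypes
  assignment <- validate_assignment(assignment, K, ncol(observed))
  warm <- .profiles_to_matrix(warm_start_profiles)
  P <- .optimize_profiles_joint(observed, fractions, assignment, warm, config,
                                maxit = maxit)
  empty <- setdiff(seq_len(K), unique(assignment))
  # unoccupied subtypes carry no gradient; keep their warm start verbatim
  # (the optimizer only clips them into the box otherwise)
  if (length(empty)) P[, empty] <- warm[, empty]
  prof <- .profiles_from_matrix(P, rownames(observed))
  attr(prof, "empty_subtypes") <- empty
  attr(prof, "objective") <- attr(P, "objective")
  prof
}

#' Reassign samples to subtypes (step 1.2)
#'
#' Each sample is assigned the cancer subtype minimizing its own squared
#' log-reconstruction error, by exhaustive enumeration over the K subtypes.
#' Ties break toward the lowest subtype index. The total objective can never
#' increase.
#'
#' @inheritParams compute_mse
#' @return Integer vector of labels in 1..K.
#' @export
reassign_subtypes <- function(observed, profiles, fractions) {
  validate_expression_matrix(observed)
  validate_fractions(fractions)
  K <- profiles$n_subtypes
  G <- nrow(observed)
  n <- ncol(observed)
  u <- exp(profiles$immune); v <- exp(profiles$stromal)
  base <- tcrossprod(u, fractions[, "immune"]) + tcrossprod(v, fractions[, "stromal"])
  A <- exp(profiles$cancer)
  sse <- matrix(NA_real_, K, n)
  for (k in seq_len(K)) {
    M <- base + tcrossprod(A[, k], fractions[, "cancer"])
    R <- observed - log(M)
    sse[k, ] <- colSums(R * R)
  }
  # first index attaining the column minimum (ties -> lowest subtype)
  as.integer(max.col(-t(sse), ties.method = "first"))
}

#' Inner optimization layer (steps 1.0-1.3)
#'
#' Fits the single-subtype model, clusters the residuals to initialize the
#' subtype labels, then alternates profile optimization and subtype
#' reassignment until the relative objective change falls below
#' `rel_tol_inner`, the assignment stops changing, or the iteration cap is
#' reached. When `state` (a previous fit state) is supplied, the
#' single-subtype / K-means initialization is skipped and the loop warm
#' starts from that state's profiles and assignment, so the objective can
#' only descend across outer iterations.
#'
#' @inheritParams fit_single_subtype
#' @param n_subtypes Number of cancer subtypes K.
#' @param state Optional warm-start state (list with `profiles`,
#'   `assignment`).
#' @return A list with `profiles`, `assignment`, `objective` (sum variant),
#'   `trace` (objective after each accepted step), `iterations`, and
#'   `converged`.
#' @export
run_inner_loop <- function(observed, fractions, n_subtypes,
                           config = declust_control(), state = NULL) {
  validate_expression_matrix(observed)
  validate_fractions(fractions)
  K <- as.integer(n_subtypes)
  if (K > ncol(observed)) stop("more subtypes than samples")

  if (is.null(state)) {
    p1 <- fit_single_subtype(observed, fractions, config)
    r <- compute_residuals(observed, p1, fractions, rep(1L, ncol(observed)))
    assignment <- init_subtypes(r, K, config)
    warm <- .profiles_from_matrix(
      cbind(p1$cancer[, rep(1L, K), drop = FALSE], p1$immune, p1$stromal),
      rownames(observed))
  } else {
    assignment <- validate_assignment(state$assignment, K, ncol(observed))
    warm <- state$profiles
  }

  profiles <- warm
  obj <- compute_mse(observed, profiles, fractions, assignment)
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < config$max_inner_iter) {
    it <- it + 1L
    profiles <- optimize_profiles(observed, fractions, assignment, profiles, config)
    new_assignment <- reassign_subtypes(observed, profiles, fractions)

    empty <- setdiff(seq_len(K), unique(new_assignment))
    if (length(empty) && K > 1L) {
      # re-seed each collapsed subtype at the worst-reconstructed sample,
      # then give profiles one extra pass
      r <- compute_residuals(observed, profiles, fractions, new_assignment)
      worst <- order(-colSums(r * r))
      P <- .profiles_to_matrix(profiles)
      for (i in seq_along(empty)) P[, empty[i]] <- observed[, worst[i]]
      cand_prof <- optimize_profiles(observed, fractions, new_assignment,
                                     .profiles_from_matrix(P, rownames(observed)),
                                     config)
      cand_assignment <- reassign_subtypes(observed, cand_prof, fractions)
      cand_obj <- compute_mse(observed, cand_prof, fractions, cand_assignment)
      if (cand_obj <= compute_mse(observed, profiles, fractions, new_assignment)) {
        profiles <- cand_prof
        new_assignment <- cand_assignment
      }
    }

    new_obj <- compute_mse(observed, profiles, fractions, new_assignment)
    trace <- c(trace, new_obj)
    unchanged <- all(new_assignment == assignment)
    assignment <- new_assignment
    rel <- if (obj > 0) abs(obj - new_obj) / obj else 0
    obj <- new_obj
    if (unchanged || rel < config$rel_tol_inner) {
      converged <- TRUE
      break
    }
  }
  list(profiles = profiles, assignment = assignment, objective = obj,
       trace = trace, iterations = it, converged = converged)
}

#' Optimize per-sample compartment fractions (step 2)
#'
#' For each sample independently, minimizes the squared log-reconstruction
#' error over (f_immune, f_stromal) in the unit box with
#' f_cancer = 1 - f_immune - f_stromal, using L-BFGS-B with analytic
#' gradients and a soft feasibility penalty keeping the cancer fraction
#' non-negative; the result is projected onto the simplex. A sample keeps
#' its warm start whenever the optimized value would be worse.
#'
#' @inheritParams compute_mse
#' @param warm_start_fractions Samples x 3 warm-start fraction matrix.
#' @param config A [declust_control()] object.
#' @return Samples x 3 fraction matrix on the simplex; never worse than the
#'   warm start in total objective.
#' @export
optimize_fractions <- function(observed, profiles, assignment,
                               warm_start_fractions, config = declust_control()) {
  validate_expression_matrix(observed)
  validate_fractions(warm_start_fractions)
  K <- profiles$n_subtypes
  n <- ncol(observed)
  assignment <- validate_assignment(assignment, K, n)
  A <- exp(profiles$cancer); u <- exp(profiles$immune); v <- exp(profiles$stromal)
  floor_c <- config$min_cancer_fraction
  pen <- 1e4

  out <- warm_start_fractions
  n_fallback <- 0L
  for (j in seq_len(n)) {
    a <- A[, assignment[j]]
    o <- observed[, j]
    sample_obj <- function(fi, fs) {
      f <- project_simplex3(matrix(c(1 - fi - fs, fi, fs), 1L))
      m <- a * f[1L] + u * f[2L] + v * f[3L]
      sum((o - log(m))^2)
    }
    fn <- function(p) {
      fc <- 1 - p[1L] - p[2L]
      m <- pmax(a * max(fc, 0) + u * p[1L] + v * p[2L], 1e-12)
      sum((o - log(m))^2) + pen * max(floor_c - fc, 0)^2
    }
    gr <- function(p) {
      fc <- 1 - p[1L] - p[2L]
      m <- pmax(a * max(fc, 0) + u * p[1L] + v * p[2L], 1e-12)
      w <- -2 * (o - log(m)) / m
      ac <- if (fc > 0) a else 0 * a
      gpen <- if (fc < floor_c) 2 * pen * (floor_c - fc) else 0
      c(sum(w * (u - ac)) + gpen, sum(w * (v - ac)) + gpen)
    }
    p0 <- c(out[j, "immune"], out[j, "stromal"])
    res <- tryCatch(
      stats::optim(p0, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(maxit = 100L)),
      error = function(e) NULL
    )
    warm_val <- sample_obj(p0[1L], p0[2L])
    if (!is.null(res) && is.finite(res$value)) {
      cand <- project_simplex3(matrix(c(max(1 - sum(res$par), 0), res$par), 1L))
      cand_val <- sample_obj(cand[2L], cand[3L])
      if (cand_val <= warm_val) {
        out[j, ] <- cand
        next
      }
    }
    n_fallback <- n_fallback + 1L
  }
  out <- project_simplex3(out)
  attr(out, "n_fallback") <- n_fallback
  out
}

# Joint quasi-Newton refinement of the continuous variables (all profile
# values and all fractions) at a fixed subtype assignment. Block alternation
# crawls along the ridge where a common rescaling of a subtype's linear
# profile trades off against its members' cancer fractions; optimizing the
# blocks jointly resolves it. Same objective, same box constraints, same
# fixed points; the assignment block is untouched.
#' @keywords internal
.refine_joint <- function(observed, profiles, fractions, assignment, config,
                          maxit = config$refine_maxit) {
  G <- nrow(observed); n <- ncol(observed); K <- profiles$n_subtypes
  np <- G * (K + 2L)
  idx_by_k <- lapply(seq_len(K), function(k) which(assignment == k))
  rng_lo <- apply(observed, 1L, min) - config$profile_bounds_pad
  rng_hi <- apply(observed, 1L, max) + config$profile_bounds_pad
  lower <- c(rep(rng_lo, K + 2L), rep(0, 2L * n))
  upper <- c(rep(rng_hi, K + 2L), rep(1, 2L * n))
  pen <- 1e4
  floor_c <- config$min_cancer_fraction
  ones <- rep(1, n)

  cache <- new.env(parent = emptyenv())
  eval_point <- function(par) {
    if (!identical(par, cache$par)) {
      L <- exp(matrix(par[seq_len(np)], G))
      fi <- par[np + seq_len(n)]; fs <- par[np + n + seq_len(n)]
      fc <- pmax(1 - fi - fs, 0)
      cache$par <- par
      cache$L <- L
      cache$fi <- fi
      cache$fs <- fs
      cache$M <- pmax(L[, assignment, drop = FALSE] * rep(fc, each = G) +
                        tcrossprod(L[, K + 1L], fi) +
                        tcrossprod(L[, K + 2L], fs), 1e-12)
    }
    cache
  }
  fn <- function(par) {
    cc <- eval_point(par)
    R <- observed - log(cc$M)
    sum(R * R) + pen * sum(pmax(floor_c - (1 - cc$fi - cc$fs), 0)^2)
  }
  gr <- function(par) {
    cc <- eval_point(par)
    L <- cc$L
    fi <- cc$fi; fs <- cc$fs
    fcr <- 1 - fi - fs
    fc <- pmax(fcr, 0)
    M <- cc$M
    W <- -2 * (observed - log(M)) / M
    Tc <- W * rep(fc, each = G)
    gcan <- matrix(0, G, K)
    for (k in seq_len(K)) {
      j <- idx_by_k[[k]]
      if (length(j)) gcan[, k] <- rowSums(Tc[, j, drop = FALSE]) * L[, k]
    }
    gi <- as.vector(W %*% fi) * L[, K + 1L]
    gs <- as.vector(W %*% fs) * L[, K + 2L]
    Aasg <- L[, assignment, drop = FALSE] * rep(as.numeric(fcr > 0), each = G)
    gpen <- ifelse(fcr < floor_c, 2 * pen * (floor_c - fcr), 0)
    gfi <- colSums(W * (tcrossprod(L[, K + 1L], ones) - Aasg)) + gpen
    gfs <- colSums(W * (tcrossprod(L[, K + 2L], ones) - Aasg)) + gpen
    c(gcan, gi, gs, gfi, gfs)
  }

  warm_P <- pmin(pmax(.profiles_to_matrix(profiles),
                      matrix(rng_lo, G, K + 2L)), matrix(rng_hi, G, K + 2L))
  par0 <- c(as.vector(warm_P), fractions[, "immune"], fractions[, "stromal"])
  f0 <- compute_mse(observed, profiles, fractions, assignment)
  res <- tryCatch(
    stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = maxit, factr = config$optim_factr)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value)) {
    return(list(profiles = profiles, fractions = fractions, improved = FALSE))
  }
  fi <- res$par[np + seq_len(n)]; fs <- res$par[np + n + seq_len(n)]
  fr <- project_simplex3(cbind(cancer = pmax(1 - fi - fs, 0),
                               immune = fi, stromal = fs))
  rownames(fr) <- rownames(fractions)
  prof <- .profiles_from_matrix(matrix(res$par[seq_len(np)], G),
                                rownames(observed))
  # projection can shift the objective; accept only true improvements
  f1 <- compute_mse(observed, prof, fr, assignment)
  if (f1 <= f0) {
    list(profiles = prof, fractions = fr, improved = TRUE)
  } else {
    list(profiles = profiles, fractions = fractions, improved = FALSE)
  }
}

#' Full two-layer fit at a fixed number of subtypes
#'
#' Runs the complete pipeline: grid search for the marker scaling constants
#' (unless supplied), marker-based fraction initialization, then alternation
#' of the inner layer (profiles + subtype labels) with per-sample fraction
#' optimization until the relative change of the objective falls below
#' `rel_tol_outer` or `max_outer_iter` is reached.
#'
#' @param observed Genes x samples log expression matrix (already
#'   variance-filtered; see [filter_low_variance_genes()]).
#' @param markers A [marker_set()] of immune and stromal marker genes.
#' @param n_subtypes Number of cancer subtypes K.
#' @param config A [declust_control()] object.
#' @param constants Optional pre-determined [scaling_constants()]; when
#'   `NULL` they are found by [grid_search_constants()].
#' @return An object of class `declust_fit`: `profiles`, `fractions`,
#'   `assignment`, `objective` (sum variant), `mse_mean`, `n_subtypes`,
#'   `constants`, `history` (outer objective trace and inner traces),
#'   `converged`, `config`.
#' @export
run_declust <- function(observed, markers, n_subtypes,
                        config = declust_control(), constants = NULL) {
  validate_expression_matrix(observed)
  K <- as.integer(n_subtypes)
  if (K < 1L) stop("n_subtypes must be >= 1")
  if (is.null(constants)) {
    gs <- grid_search_constants(observed, markers, K, config)
    constants <- gs$constants
  }
  fractions <- init_fractions_from_markers(observed, markers, constants)

  state <- NULL
  outer_trace <- numeric(0)
  inner_traces <- list()
  obj <- Inf
  converged <- FALSE
  it <- 0L
  while (it < config$max_outer_iter) {
    it <- it + 1L
    state <- run_inner_loop(observed, fractions, K, config, state = state)
    fractions <- optimize_fractions(observed, state$profiles, state$assignment,
                                    fractions, config)
    ref <- .refine_joint(observed, state$profiles, fractions,
                         state$assignment, config)
    if (ref$improved) {
      state$profiles <- ref$profiles
      fractions <- ref$fractions
    }
    new_obj <- compute_mse(observed, state$profiles, fractions, state$assignment)
    outer_trace <- c(outer_trace, new_obj)
    inner_traces[[it]] <- state$trace
    rel <- if (is.finite(obj) && obj > 0) abs(obj - new_obj) / obj else Inf
    obj <- new_obj
    if (rel < config$rel_tol_outer) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("outer loop reached max_outer_iter without meeting rel_tol_outer")
  }
  structure(
    list(profiles = state$profiles, fractions = fractions,
         assignment = state$assignment, objective = obj,
         mse_mean = obj / length(observed), n_subtypes = K,
         constants = constants,
         history = list(outer = outer_trace, inner = inner_traces,
                        outer_iterations = it),
         converged = converged, config = config,
         gene_ids = rownames(observed), sample_ids = colnames(observed)),
    class = "declust_fit"
  )
}

#' @export
print.declust_fit <- function(x, ...) {
  cat(sprintf(
    "declust fit: %d genes, %d samples, K = %d\n  objective (sum) = %.6g, mean = %.6g, converged = %s\n",
    length(x$gene_ids), length(x$sample_ids), x$n_subtypes,
    x$objective, x$mse_mean, x$converged))
  cat("  subtype sizes:", paste(tabulate(x$assignment, x$n_subtypes), collapse = ", "), "\n")
  invisible(x)
}
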