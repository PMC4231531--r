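# Independent oracles used across the suite. These deliberately avoid the
# package's simplex/MILP code paths: LP optima come from exhaustive vertex
# enumeration, GPR semantics from R's own boolean evaluator, and the
# combinatorial searches from plain subset enumeration.

## Brute-force LP oracle: max obj'v s.t. S v = 0, lb <= v <= ub, by
## enumerating all basic solutions (choose rank(S) basic columns, pin the
## rest at either bound). Finite bounds required.
oracle_lp_max <- function(obj, S, lb, ub, b = rep(0, nrow(as.matrix(S))),
                          tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  qrt <- qr(t(S))
  r <- qrt$rank
  rows <- sort(qrt$pivot[seq_len(r)])
  Sr <- S[rows, , drop = FALSE]
  br <- b[rows]
  best <- -Inf
  feas <- function(x) {
    all(x >= lb - tol) && all(x <= ub + tol) &&
      max(abs(S %*% x - b)) <= tol * max(1, max(abs(x)))
  }
  ## all variables nonbasic (r == 0)
  if (r == 0L) {
    x <- ifelse(obj > 0, ub, lb)
    return(sum(obj * x))
  }
  basics <- utils::combn(n, r, simplify = FALSE)
  nb_count <- n - r
  for (Bidx in basics) {
    SB <- Sr[, Bidx, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    Nidx <- setdiff(seq_len(n), Bidx)
    for (mask in seq_len(2^nb_count) - 1L) {
      xN <- numeric(nb_count)
      for (k in seq_len(nb_count)) {
        at_ub <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L
        xN[k] <- if (at_ub) ub[Nidx[k]] else lb[Nidx[k]]
      }
      rhs <- br - if (nb_count > 0L) {
        as.vector(Sr[, Nidx, drop = FALSE] %*% xN)
      } else 0
      xB <- tryCatch(solve(SB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n)
      x[Bidx] <- xB
      x[Nidx] <- xN
      if (feas(x)) best <- max(best, sum(obj * x))
    }
  }
  best
}

oracle_fba_mu <- function(model) {
  S <- as.matrix(build_stoich_matrix(model))
  obj <- as.numeric(model$rxns$id == model$objective_id)
  oracle_lp_max(obj, S, model$rxns$lb, model$rxns$ub)
}

## Independent GPR evaluator: turn the rule string into an R expression and
## let R's parser/evaluator decide.
oracle_gpr_eval <- function(rule_string, present) {
  if (!nzchar(trimws(rule_string))) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule_string,
                                      ignore.case = TRUE),
               ignore.case = TRUE)
  genes <- setdiff(strsplit(gsub("[()]", " ", rule_string),
                            "[[:space:]]+")[[1]],
                   c("", "and", "or", "AND", "OR"))
  env <- new.env()
  for (g in genes) assign(g, g %in% present, envir = env)
  eval(parse(text = expr), envir = env)
}

## Random GPR tree generator (structure built directly, not via parse_gpr)
random_gpr_tree <- function(genes, depth) {
  if (depth == 0L || stats::runif(1) < 0.35) {
    return(list(op = "gene", gene = sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  list(op = op, args = lapply(seq_len(k), function(i)
    random_gpr_tree(genes, depth - 1L)))
}

eval_tree <- function(node, present) {
  switch(node$op,
    gene = node$gene %in% present,
    and = all(vapply(node$args, eval_tree, logical(1), present = present)),
    or = any(vapply(node$args, eval_tree, logical(1), present = present)))
}

tree_genes <- function(node) {
  if (node$op == "gene") return(node$gene)
  unique(unlist(lapply(node$args, tree_genes)))
}

## Exhaustive gap-fill oracle: smallest subset of candidates restoring
## growth >= target.
oracle_gapfill_min_size <- function(model, medium, cands, target,
                                    max_size = 3L) {
  m0 <- apply_medium(model, medium)
  for (k in seq_len(min(max_size, length(cands)))) {
    for (s in utils::combn(length(cands), k, simplify = FALSE)) {
      sol <- solve_fba(add_reactions(m0, cands[s]))
      if (sol$status == "optimal" && sol$objective_value >= target - 1e-9) {
        return(k)
      }
    }
  }
  NA_integer_
}

## Sign-pattern search for ATP-producing closed flux modes: close all
## exchanges, then for every direction assignment of the reversible
## reactions check whether the dissipation flux can exceed eps inside that
## orthant.
oracle_cycle_exists <- function(model, dissipation = c(atp_c = -1, adp_c = 1),
                                eps = 1e-6) {
  m <- model
  for (rid in m$rxns$id[m$rxns$kind == "exchange"]) {
    k <- match(rid, m$rxns$id)
    m$rxns$lb[k] <- 0; m$rxns$ub[k] <- 0
  }
  m <- add_reactions(m, reaction("diss__", dissipation, lb = 0, ub = 1000))
  rev_idx <- which(m$rxns$lb < 0 & m$rxns$ub > 0)
  S <- as.matrix(build_stoich_matrix(m))
  obj <- as.numeric(m$rxns$id == "diss__")
  n_rev <- length(rev_idx)
  stopifnot(n_rev <= 12)
  for (mask in seq_len(2^n_rev) - 1L) {
    lb <- m$rxns$lb; ub <- m$rxns$ub
    for (k in seq_len(n_rev)) {
      fw <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L
      if (fw) lb[rev_idx[k]] <- 0 else ub[rev_idx[k]] <- 0
    }
    val <- oracle_lp_max(obj, S, lb, ub)
    if (is.finite(val) && val > eps) return(TRUE)
  }
  FALSE
}

## Brute-force differential-deletion enumeration (no pruning): returns the
## minimal differential sets as sorted unit-label strings.
oracle_compare <- function(model_a, model_b, orthologs, medium,
                           max_set_size = 2L, eps = 1e-6) {
  ma <- apply_medium(model_a, strainscope:::medium_restrict(medium, model_a))
  mb <- apply_medium(model_b, strainscope:::medium_restrict(medium, model_b))
  units <- strainscope:::deletion_units(model_a, model_b, orthologs)
  nu <- length(units)
  mu <- function(m, genes) {
    if (length(genes) == 0L) {
      s <- solve_fba(m)
    } else {
      s <- solve_fba(knock_out(m, genes))
    }
    if (s$status == "optimal") s$objective_value else 0
  }
  diff_sets <- list()
  for (size in seq_len(max_set_size)) {
    for (idx in utils::combn(nu, size, simplify = FALSE)) {
      ga <- unlist(lapply(units[idx], `[[`, "genes_a"))
      gb <- unlist(lapply(units[idx], `[[`, "genes_b"))
      dead_a <- mu(ma, ga) < eps
      dead_b <- mu(mb, gb) < eps
      if (dead_a != dead_b) {
        diff_sets[[length(diff_sets) + 1L]] <- idx
      }
    }
  }
  ## keep only minimal sets
  minimal <- Filter(function(s) {
    !any(vapply(diff_sets, function(t)
      length(t) < length(s) && all(t %in% s), logical(1)))
  }, diff_sets)
  sort(vapply(minimal, function(idx) {
    paste(sort(vapply(units[idx], `[[`, character(1), "label")),
          collapse = "+")
  }, character(1)))
}

comparison_set_labels <- function(cmp) {
  sort(vapply(cmp$sets, function(s)
    paste(sort(s$units), collapse = "+"), character(1)))
}
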