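#' Hierarchical clustering of mixed-type variables
#'
#' Agglomerates quantitative and qualitative variables into clusters of
#' mutually related variables, the dimension-reduction step run
#' separately at each level before model selection. A cluster's
#' homogeneity is the leading eigenvalue of its standardized
#' mixed-encoded block: the sum over member variables of the squared
#' correlation (quantitative members) or correlation ratio eta-squared
#' (qualitative members) with the cluster's first principal component.
#' Each merge picks the pair of clusters whose union loses the least
#' homogeneity; a singleton cluster has homogeneity exactly 1, so the
#' p-cluster partition has total homogeneity p.
#'
#' Quantitative variables are centered and scaled to unit variance;
#' qualitative variables are expanded to centered indicator columns
#' scaled by the inverse square root of the category frequency (the
#' mixed-PCA convention), which makes a lone qualitative variable
#' perfectly represented by its own leading component.
#'
#' @param table A `micro_table`, `macro_table`, or data frame.
#' @param specs Variable specs; defaults to those attached to the table.
#' @param level `"individual"` or `"group"`; inferred from the table
#'   class when possible.
#' @return An object of class `"cluster_tree"`: list with `merges` (data
#'   frame with columns `a`, `b` — hclust-style signed indices, negative
#'   = leaf — and `loss`, the homogeneity lost by the merge), `labels`
#'   (variable names), `level`, and `dropped` (zero-variance variables
#'   excluded with a warning).
#' @export
cluster_variables <- function(table, specs = attr(table, "specs"),
                              level = NULL) {
  if (is.null(level)) {
    level <- if (inherits(table, "micro_table")) "individual"
             else if (inherits(table, "macro_table")) "group"
             else stop("supply level for a plain data frame")
  }
  specs <- specs_at_level(specs, level)
  blocks <- mixed_blocks(table, specs)
  dropped <- names(blocks)[vapply(blocks, is.null, logical(1))]
  if (length(dropped)) {
    warning("zero-variance variable(s) excluded from clustering: ",
            paste(dropped, collapse = ", "))
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  }
  p <- length(blocks)
  if (p < 2) stop("need at least 2 usable variables to cluster")
  labels <- names(blocks)

  # active[[i]]: list(members = leaf indices, h = homogeneity, id = signed
  # hclust-style id of the node representing this cluster)
  active <- lapply(seq_len(p), function(i)
    list(members = i, h = 1, id = -i))
  homog <- function(members)
    cluster_homogeneity(do.call(cbind, blocks[members]))

  merges <- data.frame(a = integer(), b = integer(), loss = numeric())
  # pairwise merged homogeneity cache
  pairh <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    pairh[i, j] <- homog(c(i, j))

  keys <- seq_len(p)  # positions into active that are alive
  step <- 0L
  while (length(keys) > 1) {
    best <- NULL; best_loss <- Inf
    for (ii in seq_along(keys)[-length(keys)]) {
      for (jj in (ii + 1):length(keys)) {
        a <- keys[ii]; b <- keys[jj]
        hu <- pairh[min(a, b), max(a, b)]
        loss <- active[[a]]$h + active[[b]]$h - hu
        if (loss < best_loss - 1e-12) {
          best_loss <- loss; best <- c(a, b); best_h <- hu
        }
      }
    }
    step <- step + 1L
    a <- best[1]; b <- best[2]
    merges <- rbind(merges, data.frame(
      a = active[[a]]$id, b = active[[b]]$id, loss = max(0, best_loss)))
    active[[a]] <- list(members = c(active[[a]]$members, active[[b]]$members),
                        h = best_h, id = step)
    keys <- setdiff(keys, b)
    for (o in setdiff(keys, a)) {
      pairh[min(a, o), max(a, o)] <-
        homog(c(active[[a]]$members, active[[o]]$members))
    }
  }
  structure(list(merges = merges, labels = labels, level = level,
                 blocks = blocks),
            class = "cluster_tree")
}

# Standardized mixed encoding of each variable, scaled by 1/sqrt(n) so a
# single quantitative column has unit sum of squares and a qualitative
# variable's block has leading eigenvalue 1. NULL for constant variables.
mixed_blocks <- function(table, specs) {
  n <- nrow(table)
  out <- list()
  for (s in specs) {
    v <- table[[s$name]]
    if (is_quantitative(s)) {
      x <- as.numeric(v)
      sdp <- sqrt(mean((x - mean(x))^2))
      if (sdp < 1e-12) out[s$name] <- list(NULL)
      else out[[s$name]] <- matrix((x - mean(x)) / (sdp * sqrt(n)),
                                   ncol = 1)
    } else {
      lab <- as.character(v)
      cats <- intersect(s$categories, unique(lab))
      if (length(cats) < 2) { out[s$name] <- list(NULL); next }
      m <- vapply(cats, function(cat) {
        ind <- as.numeric(lab == cat)
        pc <- mean(ind)
        (ind - pc) / sqrt(pc * n)
      }, numeric(n))
      out[[s$name]] <- m
    }
  }
  out
}

# Leading eigenvalue of M'M for a standardized block.
cluster_homogeneity <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  d[1]^2
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> ", length(x$labels), " ", x$level,
      "-level variables, ", nrow(x$merges), " merges\n", sep = "")
  invisible(x)
}

#' Cut a variable-cluster tree into K clusters
#'
#' Replays the merge history until K clusters remain.
#'
#' @param tree A `"cluster_tree"`.
#' @param K Number of clusters, between 1 and the number of variables.
#' @return An object of class `"variable_partition"`: list with `K`,
#'   `assignment` (named integer vector, variable -> cluster id, ids
#'   numbered by smallest member index), and `homogeneity` (total
#'   criterion value, between 1 and p).
#' @export
cut_tree <- function(tree, K) {
  p <- length(tree$labels)
  stopifnot(K >= 1, K <= p)
  node_members <- list()               # merge step -> leaf members
  member <- seq_len(p)                 # leaf -> current cluster label
  for (s in seq_len(p - 1)) {
    a <- tree$merges$a[s]; b <- tree$merges$b[s]
    ma <- if (a < 0) -a else node_members[[a]]
    mb <- if (b < 0) -b else node_members[[b]]
    node_members[[s]] <- c(ma, mb)
    if (s <= p - K) {
      lab <- min(member[c(ma, mb)])
      member[c(ma, mb)] <- lab
    }
  }
  ids <- match(member, sort(unique(member)))
  names(ids) <- tree$labels
  h <- sum(vapply(split(seq_len(p), ids), function(m)
    cluster_homogeneity(do.call(cbind, tree$blocks[m])), numeric(1)))
  structure(list(K = K, assignment = ids, homogeneity = h, tree = tree),
            class = "variable_partition")
}

#' @export
print.variable_partition <- function(x, ...) {
  cat("<variable_partition> K=", x$K, " homogeneity=",
      signif(x$homogeneity, 5), "\n", sep = "")
  for (k in sort(unique(x$assignment)))
    cat("  [", k, "] ", paste(names(x$assignment)[x$assignment == k],
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a cluster tree to a Newick-like string
#'
#' Branch lengths are the homogeneity losses of the merges, giving a
#' plain-text dendrogram usable with standard tree tools.
#'
#' @param tree A `"cluster_tree"`.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  rep_of <- character(nrow(tree$merges))
  nm <- function(id, loss) {
    lab <- if (id < 0) tree$labels[-id] else rep_of[id]
    paste0(lab, ":", format(loss, digits = 8))
  }
  for (s in seq_len(nrow(tree$merges))) {
    l <- tree$merges$loss[s]
    rep_of[s] <- paste0("(", nm(tree$merges$a[s], l / 2), ",",
                        nm(tree$merges$b[s], l / 2), ")")
  }
  paste0(rep_of[nrow(tree$merges)], ";")
}

#' Pick one representative variable per cluster
#'
#' The default representative is the member with the highest squared
#' loading (squared correlation or correlation ratio) on its cluster's
#' leading synthetic component. Substantive overrides — e.g. preferring
#' the variable most actionable as an intervention lever — take
#' precedence per cluster.
#'
#' @param partition A `"variable_partition"`.
#' @param overrides Optional character vector of variable names to force
#'   as representatives of their clusters.
#' @return Character vector, one variable name per cluster, ordered by
#'   cluster id.
#' @export
pick_representatives <- function(partition, overrides = NULL) {
  tree <- partition$tree
  asg <- partition$assignment
  reps <- character(0)
  if (!is.null(overrides)) {
    unknown <- setdiff(overrides, names(asg))
    if (length(unknown))
      stop("override(s) not among clustered variables: ",
           paste(unknown, collapse = ", "))
    ocl <- asg[overrides]
    if (anyDuplicated(ocl))
      stop("override conflict: two picks in cluster ",
           paste(unique(ocl[duplicated(ocl)]), collapse = ", "))
  }
  for (k in sort(unique(asg))) {
    members <- names(asg)[asg == k]
    if (!is.null(overrides) && any(overrides %in% members)) {
      reps <- c(reps, intersect(overrides, members))
      next
    }
    if (length(members) == 1) { reps <- c(reps, members); next }
    M <- do.call(cbind, tree$blocks[members])
    u1 <- svd(M, nu = 1, nv = 0)$u[, 1]
    load <- vapply(members, function(v) {
      B <- tree$blocks[[v]]
      # squared multiple correlation of the component with the variable's
      # block = r^2 for quantitative, eta^2 for qualitative (block columns
      # are orthogonal-equivalent projectors after mixed scaling)
      f <- stats::lm.fit(cbind(1, B), u1)
      1 - sum(f$residuals^2) / sum((u1 - mean(u1))^2)
    }, numeric(1))
    reps <- c(reps, members[which.max(load)])
  }
  unname(reps)
}
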