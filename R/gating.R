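#' Define a polygon gate in scalar-feature space
#'
#' @param name Gate name.
#' @param x_feature,y_feature Names of scalar features (columns of the
#'   event table's scalars or fluorescence).
#' @param vertices Numeric matrix with >= 3 rows and 2 columns (x, y)
#'   describing a simple polygon.
#' @return An object of class `isgc_gate`.
#' @export
gate <- function(name, x_feature, y_feature, vertices) {
  vertices <- as.matrix(vertices)
  stop_if_not(ncol(vertices) == 2 && nrow(vertices) >= 3,
              "vertices must be an n x 2 matrix with n >= 3")
  stop_if_not(all(is.finite(vertices)), "vertices must be finite")
  structure(list(name = name, x_feature = x_feature,
                 y_feature = y_feature, vertices = vertices),
            class = "isgc_gate")
}

#' Rectangular gate
#'
#' @inheritParams gate
#' @param xlim,ylim Length-2 numeric ranges.
#' @return An `isgc_gate`.
#' @export
rect_gate <- function(name, x_feature, y_feature, xlim, ylim) {
  gate(name, x_feature, y_feature,
       rbind(c(xlim[1], ylim[1]), c(xlim[2], ylim[1]),
             c(xlim[2], ylim[2]), c(xlim[1], ylim[2])))
}

# Scalar feature lookup across the scalars / fluorescence / info blocks.
get_feature <- function(events, name) {
  for (block in list(events$scalars, events$fluorescence)) {
    if (name %in% colnames(block)) return(block[[name]])
  }
  stop("feature '", name, "' not found in event scalars or fluorescence",
       call. = FALSE)
}

# Crossing-number point-in-polygon with boundary points counted inside.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- abs(cross) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a gate to an event table
#'
#' @param events An [isgc_events()] table.
#' @param g An [gate()] object.
#' @return Logical inclusion mask (boundary points count as inside).
#' @export
apply_gate <- function(events, g) {
  stop_if_not(inherits(g, "isgc_gate"), "g must be an isgc_gate")
  px <- get_feature(events, g$x_feature)
  py <- get_feature(events, g$y_feature)
  point_in_polygon(px, py, g$vertices[, 1], g$vertices[, 2])
}

#' Fluorescence threshold labeling rule
#'
#' @param channel Fluorescence channel name.
#' @param threshold Intensity threshold (strict: an event is positive iff
#'   its intensity exceeds the threshold).
#' @param positive_class,negative_class Label names.
#' @return An object of class `label_rule`.
#' @export
label_rule <- function(channel, threshold, positive_class = "positive",
                       negative_class = "negative") {
  stop_if_not(is_number(threshold), "threshold must be finite")
  structure(list(channel = channel, threshold = threshold,
                 positive_class = positive_class,
                 negative_class = negative_class),
            class = "label_rule")
}

#' Label events by a fluorescence threshold
#'
#' The supervision step of in silico labeling: each cell is labeled
#' positive or negative according to whether its fluorescence intensity
#' strictly exceeds the rule's threshold.
#'
#' @param events An [isgc_events()] table.
#' @param rule A [label_rule()].
#' @return Character vector of labels.
#' @export
threshold_label <- function(events, rule) {
  stop_if_not(inherits(rule, "label_rule"), "rule must be a label_rule")
  x <- get_feature(events, rule$channel)
  ifelse(x > rule$threshold, rule$positive_class, rule$negative_class)
}

#' Build a hierarchical gating scheme
#'
#' @param steps List of steps, each `list(gate = <isgc_gate>, action =
#'   "keep"|"assign", class = <name, for assign>)`.
#' @return An object of class `gating_scheme`.
#' @export
gating_scheme <- function(steps = list()) {
  for (s in steps) {
    stop_if_not(inherits(s$gate, "isgc_gate"), "each step needs a gate")
    stop_if_not(s$action %in% c("keep", "assign"),
                "action must be 'keep' or 'assign'")
    if (s$action == "assign") {
      stop_if_not(!is.null(s$class), "assign steps need a class")
    }
  }
  structure(list(steps = steps), class = "gating_scheme")
}

#' Hierarchically gate an event table into classes
#'
#' Steps are applied in order: `keep` gates restrict the active
#' population (events outside remain ungated); `assign` gates label the
#' active, still-unlabeled events inside them — the first matching assign
#' gate wins. Events never assigned end as `"ungated"`, so class counts
#' plus ungated always conserve the total.
#'
#' @param events An [isgc_events()] table.
#' @param scheme A [gating_scheme()].
#' @return Character vector of class labels (including `"ungated"`).
#' @export
hierarchical_gate <- function(events, scheme) {
  stop_if_not(inherits(scheme, "gating_scheme"),
              "scheme must be a gating_scheme")
  n <- n_events(events)
  labels <- rep("ungated", n)
  active <- rep(TRUE, n)
  for (s in scheme$steps) {
    mask <- apply_gate(events, s$gate)
    if (s$action == "keep") {
      active <- active & mask
    } else {
      sel <- active & mask & labels == "ungated"
      labels[sel] <- s$class
    }
  }
  labels
}

#' Balanced train/test split
#'
#' Draws exactly `n_train_per_class` training and `n_test_per_class` test
#' events per class, uniformly without replacement and without overlap —
#' the repeated-random-sampling protocol used for the binary
#' classification benchmarks.
#'
#' @param labels Character/factor vector of class labels.
#' @param n_train_per_class,n_test_per_class Per-class counts.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
balanced_split <- function(labels, n_train_per_class, n_test_per_class,
                           seed = 1L) {
  labels <- as.character(labels)
  need <- n_train_per_class + n_test_per_class
  with_seed(seed, {
    train <- integer(0)
    test <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < need) {
        stop("class '", cl, "' has ", length(idx),
             " events; needs ", need, call. = FALSE)
      }
      pick <- sample(idx, need)
      train <- c(train, pick[seq_len(n_train_per_class)])
      test <- c(test, pick[n_train_per_class + seq_len(n_test_per_class)])
    }
    list(train = sort(train), test = sort(test))
  })
}

#' Stratified fraction split
#'
#' Splits events into train/test stratified by class with per-class
#' training sizes `round(train_fraction * class size)`.
#'
#' @param labels Class labels.
#' @param train_fraction Fraction in (0, 1) (e.g. 0.7 for a 70/30 split).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
fraction_split <- function(labels, train_fraction, seed = 1L) {
  stop_if_not(is_number(train_fraction) && train_fraction > 0 &&
                train_fraction < 1, "train_fraction must be in (0, 1)")
  labels <- as.character(labels)
  with_seed(seed, {
    train <- integer(0)
    test <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) {
        warning("class '", cl, "' has fewer than 2 events; all to train")
        train <- c(train, idx)
        next
      }
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      pick <- sample(idx, n_tr)
      train <- c(train, pick)
      test <- c(test, setdiff(idx, pick))
    }
    list(train = sort(train), test = sort(test))
  })
}
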