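## Network statistic terms
##
## A model is specified as a character vector in a small term language:
##   "edges"            tie count
##   "gwidegree(0.25)"  geometrically weighted in-degree, fixed decay
##   "gwesp(0.25)"      geometrically weighted edgewise shared partners
##                      (transitive / outgoing-two-path shared partners)
##   "absdiff(mvpa)"    sum over ties of |x_i - x_j| for a numeric attribute
##   "nodematch(sex)"   number of ties whose endpoints share an attribute value
## Decays are fixed (never estimated); the family stays linear.

.TERM_CODES <- c(edges = 0L, gwidegree = 1L, gwesp = 2L, absdiff = 3L, nodematch = 4L)

#' Parse a vector of network statistic terms
#'
#' @param terms character vector, e.g. `c("edges", "gwesp(0.25)", "absdiff(mvpa)")`.
#' @param default_decay decay used when a geometric term omits its argument.
#' @return a `classnet_terms` object (list with `name`, `type`, `decay`,
#'   `attr`, `label` vectors).
#' @examples
#' parse_terms(c("edges", "gwesp(0.25)", "nodematch(sex)"))
#' @export
parse_terms <- function(terms, default_decay = 0.25) {
  if (inherits(terms, "classnet_terms")) return(terms)
  stopifnot(is.character(terms), length(terms) >= 1)
  m <- regmatches(terms, regexec("^\\s*([a-z_]+)\\s*(?:\\(([^)]*)\\))?\\s*$", terms))
  out <- list(name = character(0), type = integer(0), decay = numeric(0),
              attr = character(0), label = character(0))
  for (k in seq_along(terms)) {
    parts <- m[[k]]
    if (length(parts) == 0 || !(parts[2] %in% names(.TERM_CODES)))
      stop("unknown term: '", terms[k], "'", call. = FALSE)
    nm <- parts[2]
    arg <- parts[3]
    type <- .TERM_CODES[[nm]]
    decay <- 0
    attr <- NA_character_
    if (type %in% c(1L, 2L)) {
      decay <- if (nzchar(arg)) suppressWarnings(as.numeric(arg)) else default_decay
      if (is.na(decay) || decay < 0)
        stop("term '", terms[k], "': decay must be a number >= 0", call. = FALSE)
      label <- sprintf("%s(%g)", nm, decay)
    } else if (type %in% c(3L, 4L)) {
      if (!nzchar(arg))
        stop("term '", terms[k], "' requires an attribute name", call. = FALSE)
      attr <- trimws(arg)
      label <- sprintf("%s(%s)", nm, attr)
    } else {
      if (nzchar(arg)) stop("term 'edges' takes no argument", call. = FALSE)
      label <- "edges"
    }
    out$name <- c(out$name, nm)
    out$type <- c(out$type, type)
    out$decay <- c(out$decay, decay)
    out$attr <- c(out$attr, attr)
    out$label <- c(out$label, label)
  }
  structure(out, class = "classnet_terms")
}

#' @export
print.classnet_terms <- function(x, ...) {
  cat("network statistic terms:", paste(x$label, collapse = " + "), "\n")
  invisible(x)
}

# Encode terms against a node set: returns the n x p attribute matrix the
# C++ kernel reads (categorical attributes become integer codes).
encode_terms <- function(terms, attrs, node_ids) {
  terms <- parse_terms(terms)
  n <- length(node_ids)
  p <- length(terms$type)
  am <- matrix(0, n, p)
  for (t in seq_len(p)) {
    if (terms$type[t] %in% c(3L, 4L)) {
      a <- terms$attr[t]
      if (is.null(attrs) || !(a %in% names(attrs)))
        stop("term '", terms$label[t], "': attribute '", a,
             "' not found in node attributes", call. = FALSE)
      v <- attrs[[a]][match(node_ids, attrs$node_id)]
      if (terms$type[t] == 3L) {
        if (is.ordered(v) || is.factor(v)) v <- as.numeric(v)
        if (!is.numeric(v))
          stop("term '", terms$label[t], "': attribute must be numeric (or ordered)",
               call. = FALSE)
        if (anyNA(v))
          stop("term '", terms$label[t], "': missing attribute values for nodes ",
               paste(node_ids[is.na(v)], collapse = ", "), call. = FALSE)
        am[, t] <- v
      } else {
        if (anyNA(v))
          stop("term '", terms$label[t], "': missing attribute values for nodes ",
               paste(node_ids[is.na(v)], collapse = ", "), call. = FALSE)
        am[, t] <- as.numeric(factor(as.character(v)))
      }
    }
  }
  list(type = as.integer(terms$type), decay = as.numeric(terms$decay),
       attr = am, label = terms$label)
}
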