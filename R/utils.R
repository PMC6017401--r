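# Shared chemistry tables and small helpers.

# van der Waals radii (angstrom); unknown elements fall back to carbon.
.VDW <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)

# single-bond covalent radii (angstrom); fallback 0.77 with a warning.
.COV <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, H = 0.37, P = 1.10)

vdwRadius <- function(element) {
    r <- .VDW[element]
    unknown <- is.na(r)
    if (any(unknown)) {
        warning("unknown element(s) ",
                paste(unique(element[unknown]), collapse = ", "),
                "; using vdW radius 1.7 A")
        r[unknown] <- 1.7
    }
    unname(r)
}

covRadius <- function(element) {
    r <- .COV[element]
    unknown <- is.na(r)
    if (any(unknown)) {
        warning("unknown element(s) ",
                paste(unique(element[unknown]), collapse = ", "),
                "; using covalent radius 0.77 A")
        r[unknown] <- 0.77
    }
    unname(r)
}

# residue key: "<resno>:<icode>" ('' icode kept as trailing colon-free form)
resKey <- function(resno, icode = "") {
    icode[is.na(icode)] <- ""
    paste0(resno, ":", icode)
}

# order residue keys by (resno, icode) lexicographic
orderResKeys <- function(keys) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    resno <- as.integer(vapply(parts, `[`, "", 1L))
    icode <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
    keys[order(resno, icode)]
}

# element inferred from an atom name's first non-digit character
inferElement <- function(name) {
    el <- sub("^[0-9']*", "", trimws(name))
    el <- substr(el, 1L, 1L)
    toupper(el)
}

#' Sum of triangle areas of a mesh
#'
#' @param mesh a \code{\linkS4class{SurfaceMesh}}.
#' @return total area in square angstrom.
#' @export
meshArea <- function(mesh) {
    tr <- mesh@triangles
    if (nrow(tr) == 0) return(0)
    v <- mesh@vertices
    a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
    b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
    cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

triangleCentroids <- function(mesh) {
    tr <- mesh@triangles
    v <- mesh@vertices
    (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# simple union-find over 1..n (used for locked-bond body merging)
unionFind <- function(n) {
    up <- seq_len(n)
    find <- function(x) {
        while (up[x] != x) {
            up[x] <<- up[up[x]]
            x <- up[x]
        }
        x
    }
    list(find = find,
         unite = function(a, b) {
             ra <- find(a); rb <- find(b)
             if (ra != rb) up[max(ra, rb)] <<- min(ra, rb)
         },
         labels = function() vapply(seq_len(n), find, 1L))
}
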