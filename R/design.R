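# Feature manifest and design-matrix assembly. Position-level features are
# expanded into a sparse design with a priori fixed one-hot level sets, so the
# same encoding applies at training and prediction time.

.CONTEXT_ALPHABET <- c("A", "C", "G", "T")

.context_levels <- function() {
    mers <- function(k) {
        out <- ""
        for (i in seq_len(k))
            out <- as.vector(outer(out, .CONTEXT_ALPHABET, paste0))
        sort(out)
    }
    tri <- sort(as.vector(outer(outer(.CONTEXT_ALPHABET, c("C", "T"), paste0),
                                .CONTEXT_ALPHABET, paste0)))
    penta <- sort(as.vector(outer(outer(mers(2), c("C", "T"), paste0),
                                  mers(2), paste0)))
    list(center_class = c("AT", "CG"),
         trinucleotide = tri,
         pentanucleotide = penta,
         flank_left1 = .CONTEXT_ALPHABET,
         flank_right1 = .CONTEXT_ALPHABET,
         flank_left2 = mers(2),
         flank_right2 = mers(2))
}

.CONTEXT_COLUMN <- c(center_class = "centerClass", trinucleotide = "tri",
                     pentanucleotide = "penta", flank_left1 = "left1",
                     flank_right1 = "right1", flank_left2 = "left2",
                     flank_right2 = "right2")

#' Declare one model covariate
#'
#' @param name unique feature name. For \code{source = "user_track"} it must
#'   match a name in the track list handed to the assembly functions.
#' @param category \code{"sequence"}, \code{"epigenetic"},
#'   \code{"structural"} or \code{"sample_level"}. The category decides the
#'   stability-selection recurrence threshold (sequence features need a
#'   higher one) and whether the feature bypasses selection (sample-level
#'   covariates always enter the final model).
#' @param encoding \code{"onehot_context"}, \code{"binary_overlay"},
#'   \code{"continuous"} or \code{"count"}.
#' @param source \code{"computed"} or \code{"user_track"}.
#' @return one-row data.frame.
#' @export
featureSpec <- function(name,
                        category = c("sequence", "epigenetic", "structural",
                                     "sample_level"),
                        encoding = c("onehot_context", "binary_overlay",
                                     "continuous", "count"),
                        source = c("computed", "user_track")) {
    data.frame(name = name, category = match.arg(category),
               encoding = match.arg(encoding), source = match.arg(source),
               stringsAsFactors = FALSE)
}

#' Assemble the feature manifest
#'
#' Builds the declarative list of covariates for one background model:
#' computed sequence-context features, the computed 100-kb local mutation
#' rate, per-sample mutation burden, and any user-supplied tracks. The
#' default runs with no external tracks at all.
#'
#' @param tracks named list of \linkS4class{GenomicTrack} user tracks
#'   (binary tracks become binary overlays, continuous tracks z-scored
#'   continuous covariates). A track named \code{"local_rate"} is treated as
#'   the structural local-rate covariate.
#' @param context \code{"standard"} (center-base class, trinucleotide, 1-bp
#'   flanks), \code{"full"} (adds pentanucleotide and 2-bp flanks) or
#'   \code{"none"}.
#' @param localRate include the computed local mutation rate covariate.
#' @param burden include the per-sample mutation burden covariate.
#' @param trackCategory category assigned to user tracks (default
#'   \code{"epigenetic"}); recycled, or a named vector keyed by track name.
#' @return data.frame of feature specs (one row per feature).
#' @export
featureManifest <- function(tracks = list(),
                            context = c("standard", "full", "none"),
                            localRate = TRUE, burden = TRUE,
                            trackCategory = "epigenetic") {
    context <- match.arg(context)
    specs <- list()
    ctxNames <- switch(context,
        none = character(),
        standard = c("center_class", "trinucleotide",
                     "flank_left1", "flank_right1"),
        full = names(.context_levels()))
    for (nm in ctxNames)
        specs[[length(specs) + 1L]] <-
            featureSpec(nm, "sequence", "onehot_context", "computed")
    trackNames <- setdiff(names(tracks), "local_rate")
    if (length(trackNames)) {
        cats <- if (!is.null(names(trackCategory)))
            trackCategory[trackNames] else rep_len(trackCategory,
                                                   length(trackNames))
        for (i in seq_along(trackNames)) {
            tr <- tracks[[trackNames[i]]]
            specs[[length(specs) + 1L]] <- featureSpec(
                trackNames[i], cats[[i]],
                if (tr@kind == "binary") "binary_overlay" else "continuous",
                "user_track")
        }
    }
    if (localRate)
        specs[[length(specs) + 1L]] <-
            featureSpec("local_rate", "structural", "continuous", "computed")
    if (burden)
        specs[[length(specs) + 1L]] <-
            featureSpec("burden", "sample_level", "count", "computed")
    out <- do.call(rbind, specs)
    if (anyDuplicated(out$name)) .stop_config("duplicate feature names")
    out
}

## Position-level specs (everything except sample_level covariates).
.position_specs <- function(specs) specs[specs$category != "sample_level", ,
                                         drop = FALSE]

#' Assemble position-level design rows
#'
#' Expands the manifest's position-level features into a sparse design matrix
#' for the given positions: one-hot context groups with the
#' lexicographically-first level dropped as reference, binary overlays as
#' 0/1, continuous tracks z-scored with training-time parameters. The
#' function is pure: the same (genome, tracks, specs, positions) always
#' yields the same matrix.
#'
#' @param genome \code{DNAStringSet}.
#' @param tracks named list of \linkS4class{GenomicTrack}; must contain every
#'   \code{user_track} spec and, when the manifest asks for it, a
#'   \code{"local_rate"} track.
#' @param specs feature manifest (see \code{\link{featureManifest}}).
#' @param contig character vector (recycled) of contig names.
#' @param positions 1-based positions.
#' @param info encoding metadata from a previous call (prediction time);
#'   \code{NULL} at training time, when standardization parameters are
#'   estimated from these rows.
#' @return list with \code{X} (sparse \code{dgCMatrix}), \code{available}
#'   (logical; rows with no valid 5-mer context are all-NA and flagged
#'   FALSE), \code{groups} (column -> feature name), and \code{info}.
#' @importFrom Matrix sparseMatrix
#' @export
assembleDesign <- function(genome, tracks, specs, contig, positions,
                           info = NULL) {
    specs <- .position_specs(specs)
    contig <- rep_len(as.character(contig), length(positions))
    nr <- length(positions)
    lv <- .context_levels()
    fit <- is.null(info)
    if (fit) info <- list(standardize = list())

    needCtx <- any(specs$encoding == "onehot_context")
    ctx <- NULL
    if (needCtx && nr) {
        parts <- lapply(unique(contig), function(ct) {
            i <- which(contig == ct)
            cbind(row = i, sequenceContextAt(genome, ct, positions[i]))
        })
        ctx <- do.call(rbind, parts)
        ctx <- ctx[order(ctx$row), , drop = FALSE]
    }
    available <- if (!is.null(ctx)) ctx$available else rep(TRUE, nr)

    ii <- integer(); jj <- integer(); xx <- numeric()
    cn <- character(); groups <- character()
    col0 <- 0L
    for (k in seq_len(nrow(specs))) {
        nm <- specs$name[k]
        enc <- specs$encoding[k]
        if (enc == "onehot_context") {
            levels <- lv[[nm]]
            vals <- ctx[[.CONTEXT_COLUMN[[nm]]]]
            code <- match(vals, levels)
            ncol_k <- length(levels) - 1L
            hit <- which(!is.na(code) & code >= 2L)
            ii <- c(ii, hit)
            jj <- c(jj, col0 + code[hit] - 1L)
            xx <- c(xx, rep(1, length(hit)))
            cn <- c(cn, paste0(nm, "=", levels[-1L]))
            groups <- c(groups, rep(nm, ncol_k))
            col0 <- col0 + ncol_k
        } else {
            if (nm == "local_rate" || specs$source[k] == "user_track") {
                tr <- tracks[[nm]]
                if (is.null(tr))
                    .stop_config("manifest feature '", nm,
                                 "' has no matching track")
                v <- if (nr) .track_values_multi(tr, contig, positions)
                     else numeric()
            } else .stop_config("unknown computed feature: ", nm)
            if (enc == "continuous") {
                if (fit) {
                    mu <- mean(v[available]); sdv <- stats::sd(v[available])
                    if (!is.finite(sdv) || sdv == 0) sdv <- 1
                    if (!is.finite(mu)) mu <- 0
                    info$standardize[[nm]] <- c(center = mu, scale = sdv)
                }
                st <- info$standardize[[nm]] %||% c(center = 0, scale = 1)
                v <- (v - st[["center"]]) / st[["scale"]]
            }
            hit <- which(v != 0)
            ii <- c(ii, hit)
            jj <- c(jj, rep(col0 + 1L, length(hit)))
            xx <- c(xx, v[hit])
            cn <- c(cn, nm)
            groups <- c(groups, nm)
            col0 <- col0 + 1L
        }
    }
    X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, col0),
                              dimnames = list(NULL, cn))
    list(X = X, available = available, groups = groups, info = info)
}

## trackValues() for mixed contig vectors.
.track_values_multi <- function(track, contig, positions) {
    out <- numeric(length(positions))
    for (ct in unique(contig)) {
        i <- which(contig == ct)
        out[i] <- trackValues(track, ct, positions[i])
    }
    out
}
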