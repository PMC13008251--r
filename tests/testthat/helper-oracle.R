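## Independent reference HDBSCAN (scikit-learn) run through the python on
## PATH, used only as a cross-check oracle for the clustering core.

## Runs the reference implementation on a list of coordinate matrices in a
## single python invocation; returns a list of integer label vectors.
reference_hdbscan <- function(fixtures, min_cluster_size, min_samples,
                              epsilon = 0) {
  stopifnot(length(fixtures) >= 1)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  inp <- file.path(dir, "fixtures.csv")
  outp <- file.path(dir, "labels.csv")
  dat <- do.call(rbind, lapply(seq_along(fixtures), function(f)
    cbind(f, fixtures[[f]])))
  write.table(dat, inp, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, warnings, numpy as np",
    "warnings.filterwarnings('ignore')",
    "from sklearn.cluster import HDBSCAN",
    "inp, outp, mcs, ms, eps = sys.argv[1:6]",
    "dat = np.loadtxt(inp, delimiter=',')",
    "fid = dat[:, 0].astype(int)",
    "res = []",
    "for f in np.unique(fid):",
    "    X = dat[fid == f, 1:]",
    "    lab = HDBSCAN(min_cluster_size=int(mcs), min_samples=int(ms),",
    "                  cluster_selection_epsilon=float(eps),",
    "                  copy=True).fit_predict(X)",
    "    res.extend(lab.tolist())",
    "np.savetxt(outp, np.array(res, dtype=int), fmt='%d')"), script)
  status <- system2("python", c(script, inp, outp, min_cluster_size,
                                min_samples, epsilon),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("reference HDBSCAN oracle failed")
  lab <- scan(outp, integer(), quiet = TRUE)
  sizes <- vapply(fixtures, nrow, integer(1))
  split(lab, rep(seq_along(fixtures), sizes))
}

## Exact partition match up to relabelling (noise label -1 must coincide).
same_partition <- function(a, b) {
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  keep <- a != -1L
  if (!any(keep)) return(TRUE)
  ta <- table(a[keep], b[keep])
  sum(ta > 0) == length(unique(a[keep])) &&
    length(unique(a[keep])) == length(unique(b[keep]))
}
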