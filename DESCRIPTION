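Package: interpbench
Title: Synthetic Benchmarks for Interpretation of QSAR Models
Version: 0.1.0
Authors@R: person("Benchmark", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds synthetic molecular benchmark datasets with known per-atom
    ground-truth contributions, computes atom and fragment contributions from
    trained QSAR models by virtual removal (dummy-atom masking), and scores
    interpretation quality with per-molecule ranking metrics (AUC+/AUC-,
    top-n/bottom-n, contribution RMSE, top-k percentages, fragment top-2).
    Six labeling rules are provided: nitrogen count, nitrogen minus oxygen,
    correlated nitrogen plus oxygen, amide-group regression and
    classification, and a two-point 3D pharmacophore. Chemistry (SMILES
    parsing, standardization, SMARTS matching, conformer generation,
    fingerprints) and the conventional learner grid (RF, PLS, GBM, SVM) are
    delegated to a bundled Python backend using RDKit and scikit-learn; all
    dataset construction, labeling logic, masking bookkeeping, fragment
    enumeration and metrics are implemented in R.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with rdkit, scikit-learn, numpy, scipy,
    joblib available on the 'python' executable (override with the
    INTERPBENCH_PYTHON environment variable).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
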