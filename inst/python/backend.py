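"""Chemistry and learner backend for the interpbench R package.

Invoked as:  python backend.py <command> <input.json> <output.json>

All molecule payloads are SMILES strings; atom indices at this boundary are
0-based and refer to the atom order obtained by re-parsing the canonical
SMILES (the order frozen in the R-side molecule records).  Feature matrices
are exchanged as MatrixMarket files to keep JSON payloads small.
"""

import json
import sys
import warnings

warnings.filterwarnings("ignore")

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, rdMolDescriptors
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")


# ---------------------------------------------------------------- molecules

def _parse_canonical(smi):
    """Parse SMILES and return the molecule re-parsed from its canonical
    SMILES, so that atom order is the canonical-output order (stable across
    round trips with the same RDKit version)."""
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None, None
    can = Chem.MolToSmiles(mol)
    mol = Chem.MolFromSmiles(can)
    if mol is None:
        return None, None
    return mol, can


_BOND_ORDER = {
    Chem.BondType.SINGLE: 1.0,
    Chem.BondType.DOUBLE: 2.0,
    Chem.BondType.TRIPLE: 3.0,
    Chem.BondType.AROMATIC: 1.5,
}


def _mol_graph(mol):
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "symbol": a.GetSymbol(),
            "z": a.GetAtomicNum(),
            "aromatic": bool(a.GetIsAromatic()),
            "in_ring": bool(a.IsInRing()),
            "n_h": a.GetTotalNumHs(),
        })
    bonds = []
    for b in mol.GetBonds():
        bonds.append({
            "a": b.GetBeginAtomIdx(),
            "b": b.GetEndAtomIdx(),
            "order": _BOND_ORDER.get(b.GetBondType(), 1.0),
            "ring": bool(b.IsInRing()),
        })
    return atoms, bonds


def cmd_parse(job):
    out = []
    for smi in job["smiles"]:
        mol, can = _parse_canonical(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparsable SMILES"})
            continue
        atoms, bonds = _mol_graph(mol)
        out.append({
            "ok": True,
            "smiles": can,
            "mw": Descriptors.MolWt(mol),
            "n_heavy": mol.GetNumHeavyAtoms(),
            "atoms": atoms,
            "bonds": bonds,
        })
    return {"mols": out}


def cmd_parse_sdf(job):
    """Read an SDF (V2000); conformer coordinates are re-ordered to the
    canonical atom order used everywhere else."""
    out = []
    supplier = Chem.SDMolSupplier(job["path"], removeHs=True)
    for mol in supplier:
        if mol is None:
            out.append({"ok": False, "error": "unparsable SDF record"})
            continue
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        has_conf = mol.GetNumConformers() > 0
        coords0 = None
        if has_conf:
            conf = mol.GetConformer(0)
            coords0 = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                        conf.GetAtomPosition(i).z]
                       for i in range(mol.GetNumAtoms())]
        can = Chem.MolToSmiles(mol)
        order = json.loads(mol.GetProp("_smilesAtomOutputOrder")
                           .replace(",]", "]"))
        mol2 = Chem.MolFromSmiles(can)
        if mol2 is None:
            out.append({"ok": False, "error": "canonicalization failed"})
            continue
        atoms, bonds = _mol_graph(mol2)
        rec = {
            "ok": True,
            "name": name,
            "smiles": can,
            "mw": Descriptors.MolWt(mol2),
            "n_heavy": mol2.GetNumHeavyAtoms(),
            "atoms": atoms,
            "bonds": bonds,
        }
        if has_conf:
            rec["conformers"] = [[coords0[i] for i in order]]
        out.append(rec)
    return {"mols": out}


def cmd_standardize(job):
    """Largest organic fragment + neutralization, then canonical SMILES."""
    chooser = rdMolStandardize.LargestFragmentChooser()
    uncharger = rdMolStandardize.Uncharger()
    out = []
    for smi in job["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False})
            continue
        try:
            mol = chooser.choose(mol)
            mol = uncharger.uncharge(mol)
            Chem.SanitizeMol(mol)
        except Exception:
            out.append({"ok": False})
            continue
        can = Chem.MolToSmiles(mol)
        mol = Chem.MolFromSmiles(can)
        out.append({"ok": True, "smiles": can, "mw": Descriptors.MolWt(mol)})
    return {"mols": out}


def cmd_match(job):
    """SMARTS matches as unique unordered atom-index sets per pattern."""
    pats = [Chem.MolFromSmarts(s) for s in job["smarts"]]
    for s, p in zip(job["smarts"], pats):
        if p is None:
            raise ValueError("bad SMARTS: %s" % s)
    out = []
    for smi in job["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        res = []
        for p in pats:
            if mol is None:
                res.append([])
                continue
            matches = mol.GetSubstructMatches(p, uniquify=True)
            seen, keep = set(), []
            for m in matches:
                key = frozenset(m)
                if key not in seen:
                    seen.add(key)
                    keep.append(sorted(m))
            res.append(keep)
        out.append(res)
    return {"matches": out}


def cmd_conformers(job):
    """Distance-geometry (ETKDGv3) embedding; heavy-atom coordinates only.
    No minimization.  Failures reported per molecule, not raised."""
    out = []
    for i, smi in enumerate(job["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False})
            continue
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = int(job["seed"]) + i
        params.numThreads = 1
        try:
            cids = AllChem.EmbedMultipleConfs(
                molh, numConfs=int(job["max_conf"]), params=params)
        except Exception:
            cids = []
        if len(cids) == 0:
            out.append({"ok": False})
            continue
        molh = Chem.RemoveHs(molh)
        confs = []
        for cid in cids:
            conf = molh.GetConformer(cid)
            coords = [[conf.GetAtomPosition(a).x,
                       conf.GetAtomPosition(a).y,
                       conf.GetAtomPosition(a).z]
                      for a in range(molh.GetNumHeavyAtoms())]
            confs.append(coords)
        out.append({"ok": True, "conformers": confs})
    return {"mols": out}


# ------------------------------------------------------------- fingerprints

def _masked_mol(smi, mask):
    """Replace the atoms in `mask` (0-based) by dummy atoms (atomic number
    0), keeping all bonds.  Aromaticity is re-perceived; if sanitization
    fails the kekulized form is used."""
    mol = Chem.MolFromSmiles(smi)
    if not mask:
        return mol
    rw = Chem.RWMol(mol)
    for idx in mask:
        at = rw.GetAtomWithIdx(int(idx))
        at.SetAtomicNum(0)
        at.SetFormalCharge(0)
        at.SetNoImplicit(True)
    try:
        Chem.SanitizeMol(rw)
    except Exception:
        rw = Chem.RWMol(mol)
        Chem.Kekulize(rw, clearAromaticFlags=True)
        for idx in mask:
            at = rw.GetAtomWithIdx(int(idx))
            at.SetAtomicNum(0)
            at.SetFormalCharge(0)
            at.SetNoImplicit(True)
        Chem.SanitizeMol(
            rw, Chem.SanitizeFlags.SANITIZE_ALL
            ^ Chem.SanitizeFlags.SANITIZE_KEKULIZE
            ^ Chem.SanitizeFlags.SANITIZE_SETAROMATICITY)
    return rw.GetMol()


def _fp_counts(mol, family):
    if family == "AP":
        fp = rdMolDescriptors.GetAtomPairFingerprint(
            mol, minLength=1, maxLength=30)
    elif family == "MG2":
        fp = rdMolDescriptors.GetMorganFingerprint(mol, 2)
    elif family == "RDK":
        # paths of 2..4 atoms == 1..3 bonds
        fp = Chem.UnfoldedRDKFingerprintCountBased(mol, minPath=1, maxPath=3)
    elif family == "TT":
        fp = rdMolDescriptors.GetTopologicalTorsionFingerprint(mol)
    else:
        raise ValueError("unknown fingerprint family: %s" % family)
    return fp.GetNonzeroElements()


def _fp_bits(mol, family, nbits):
    if family == "AP":
        fp = rdMolDescriptors.GetHashedAtomPairFingerprintAsBitVect(
            mol, nBits=nbits, minLength=1, maxLength=30)
    elif family == "MG2":
        fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(mol, 2,
                                                            nBits=nbits)
    elif family == "RDK":
        fp = Chem.RDKFingerprint(mol, minPath=1, maxPath=3, fpSize=nbits)
    elif family == "TT":
        fp = rdMolDescriptors.GetHashedTopologicalTorsionFingerprintAsBitVect(
            mol, nBits=nbits)
    else:
        raise ValueError("unknown fingerprint family: %s" % family)
    return list(fp.GetOnBits())


def cmd_featurize(job):
    """Featurize a batch of (smiles, mask) jobs.

    counted=True : unfolded keyed counts.  If a vocabulary is supplied,
      out-of-vocabulary keys are dropped (the masking mechanism); otherwise
      the union of observed keys becomes the vocabulary (training mode).
    counted=False: folded binary fingerprint of length nbits; the
      vocabulary is the fixed bit range.

    Output: MatrixMarket file (rows = jobs) at job["mtx"], vocabulary and
    per-job count of dropped OOV features in the JSON result.  If
    job["as_mapping"] is true, per-job key->value mappings are returned in
    JSON instead of writing a matrix.
    """
    family = job["family"]
    counted = bool(job["counted"])
    nbits = int(job.get("nbits", 2048))
    vocab = job.get("vocab")
    masks = job.get("masks")
    feats = []
    for i, smi in enumerate(job["smiles"]):
        mask = masks[i] if masks else []
        mol = _masked_mol(smi, mask)
        if counted:
            raw = _fp_counts(mol, family)
            feats.append({str(k): int(v) for k, v in raw.items()})
        else:
            feats.append({str(b): 1 for b in _fp_bits(mol, family, nbits)})

    if job.get("as_mapping"):
        return {"features": feats}

    if counted:
        if vocab is None:
            keys = set()
            for f in feats:
                keys.update(f)
            vocab = sorted(keys)
    else:
        vocab = [str(b) for b in range(nbits)]
    col = {k: j for j, k in enumerate(vocab)}

    import numpy as np
    import scipy.io
    import scipy.sparse as sp
    rows, cols, vals, dropped = [], [], [], []
    for i, f in enumerate(feats):
        ndrop = 0
        for k, v in f.items():
            j = col.get(k)
            if j is None:
                ndrop += 1
                continue
            rows.append(i)
            cols.append(j)
            vals.append(v)
        dropped.append(ndrop)
    mat = sp.coo_matrix(
        (np.asarray(vals, dtype=float), (rows, cols)),
        shape=(len(feats), len(vocab)))
    scipy.io.mmwrite(job["mtx"], mat)
    return {"vocab": vocab, "n_oov_dropped": dropped}


# ------------------------------------------------------------------ models

def _make_estimator(algorithm, task, params, seed):
    from sklearn.cross_decomposition import PLSRegression
    from sklearn.ensemble import (GradientBoostingClassifier,
                                  GradientBoostingRegressor,
                                  RandomForestClassifier,
                                  RandomForestRegressor)
    from sklearn.svm import SVC, SVR
    if algorithm == "RF":
        cls = RandomForestRegressor if task == "regression" \
            else RandomForestClassifier
        return cls(random_state=seed, n_jobs=1, **params)
    if algorithm == "GBM":
        cls = GradientBoostingRegressor if task == "regression" \
            else GradientBoostingClassifier
        return cls(random_state=seed, **params)
    if algorithm == "SVM":
        if task == "regression":
            return SVR(kernel="rbf", **params)
        return SVC(kernel="rbf", probability=True, random_state=seed,
                   **params)
    if algorithm == "PLS":
        if task != "regression":
            raise ValueError("PLS is supported for regression only")
        return PLSRegression(**params)
    raise ValueError("unknown algorithm: %s" % algorithm)


def _fit_predict(est, algorithm, task, Xtr, ytr, Xte):
    import numpy as np
    dense = algorithm in ("PLS", "SVM")
    Xtr = Xtr.toarray() if dense else Xtr.tocsr()
    Xte = Xte.toarray() if dense else Xte.tocsr()
    if task == "regression":
        est.fit(Xtr, ytr)
        pred = np.asarray(est.predict(Xte)).ravel()
    else:
        est.fit(Xtr, ytr)
        proba = est.predict_proba(Xte)
        active = list(est.classes_).index("active")
        pred = proba[:, active]
    return est, pred


def _cv_score(task, y_obs, y_pred):
    import numpy as np
    y_pred = np.asarray(y_pred)
    if task == "regression":
        y_obs = np.asarray(y_obs, dtype=float)
        return -float(np.sqrt(np.mean((y_pred - y_obs) ** 2)))
    lab = np.where(y_pred >= 0.5, "active", "inactive")
    y_obs = np.asarray(y_obs)
    tp = np.sum((lab == "active") & (y_obs == "active"))
    fn = np.sum((lab != "active") & (y_obs == "active"))
    tn = np.sum((lab == "inactive") & (y_obs == "inactive"))
    fp = np.sum((lab != "inactive") & (y_obs == "inactive"))
    sens = tp / (tp + fn) if tp + fn else 0.0
    spec = tn / (tn + fp) if tn + fp else 0.0
    return float((sens + spec) / 2.0)


def cmd_fit(job):
    import numpy as np
    import scipy.io
    from joblib import dump
    from sklearn.model_selection import KFold, StratifiedKFold

    X = scipy.io.mmread(job["mtx"]).tocsr()
    task = job["task"]
    algorithm = job["algorithm"]
    seed = int(job["seed"])
    folds = int(job.get("cv_folds", 5))
    grid = job["grid"]
    if task == "regression":
        y = np.asarray(job["y"], dtype=float)
        splitter = KFold(n_splits=folds, shuffle=True, random_state=seed)
        split_arg = (X,)
    else:
        y = np.asarray(job["y"])
        splitter = StratifiedKFold(n_splits=folds, shuffle=True,
                                   random_state=seed)
        split_arg = (X, y)

    cv_table = []
    if len(grid) == 1:
        best_i, best_score = 0, None
    else:
        scores = []
        for params in grid:
            fold_scores = []
            for tr, te in splitter.split(*split_arg):
                est = _make_estimator(algorithm, task, params, seed)
                _, pred = _fit_predict(est, algorithm, task,
                                       X[tr], y[tr], X[te])
                fold_scores.append(_cv_score(task, y[te], pred))
            scores.append(float(np.mean(fold_scores)))
            cv_table.append({"params": params, "cv_score": scores[-1]})
        best_i = int(np.argmax(scores))
        best_score = scores[best_i]

    est = _make_estimator(algorithm, task, grid[best_i], seed)
    est, train_pred = _fit_predict(est, algorithm, task, X, y, X)
    dump({"estimator": est, "algorithm": algorithm, "task": task},
         job["model_out"])
    return {"best_params": grid[best_i], "cv_score": best_score,
            "cv_table": cv_table, "train_pred": [float(p) for p in train_pred]}


def cmd_predict(job):
    import numpy as np
    import scipy.io
    from joblib import load

    X = scipy.io.mmread(job["mtx"]).tocsr()
    obj = load(job["model"])
    est, algorithm, task = obj["estimator"], obj["algorithm"], obj["task"]
    if algorithm in ("PLS", "SVM"):
        X = X.toarray()
    if task == "regression":
        pred = np.asarray(est.predict(X)).ravel()
    else:
        proba = est.predict_proba(X)
        pred = proba[:, list(est.classes_).index("active")]
    return {"pred": [float(p) for p in pred]}


COMMANDS = {
    "parse": cmd_parse,
    "parse_sdf": cmd_parse_sdf,
    "standardize": cmd_standardize,
    "match": cmd_match,
    "conformers": cmd_conformers,
    "featurize": cmd_featurize,
    "fit": cmd_fit,
    "predict": cmd_predict,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: backend.py <command> <in.json> <out.json>\n")
        return 2
    cmd, inp, outp = argv[1], argv[2], argv[3]
    with open(inp) as fh:
        job = json.load(fh)
    try:
        result = COMMANDS[cmd](job)
    except Exception as exc:  # report errors as JSON, exit non-zero
        with open(outp, "w") as fh:
            json.dump({"error": "%s: %s" % (type(exc).__name__, exc)}, fh)
        return 1
    with open(outp, "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
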