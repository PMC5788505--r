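"""Cheminformatics backend for pathmapr.

Reads one JSON request on stdin, writes one JSON response on stdout.
All chemistry (SMILES parsing, Morgan fingerprints, SMIRKS reaction
application, stereoisomer enumeration) is delegated to RDKit; everything
else (Tanimoto arithmetic, statistics, scoring) lives on the R side.

Request:  {"op": <name>, ...op-specific fields...}
Response: {"ok": true, ...} or {"ok": false, "error": <message>}

Fingerprints are returned as sorted lists of 0-based on-bit indices.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdFingerprintGenerator
from rdkit.Chem.EnumerateStereoisomers import (
    EnumerateStereoisomers,
    StereoEnumerationOptions,
)

RDLogger.DisableLog("rdApp.*")


def _generator(params):
    return rdFingerprintGenerator.GetMorganGenerator(
        radius=int(params.get("radius", 2)),
        fpSize=int(params.get("nbits", 2048)),
        includeChirality=bool(params.get("chiral", True)),
    )


def _bits(gen, mol):
    return sorted(gen.GetFingerprint(mol).GetOnBits())


def _n_undefined_centers(mol):
    centers = Chem.FindMolChiralCenters(
        mol, includeUnassigned=True, useLegacyImplementation=False
    )
    return sum(1 for _, tag in centers if tag == "?")


def _stereo_bits(gen, mol, max_isomers):
    """Fingerprints of up to max_isomers distinct stereoisomer assignments
    of the unassigned centers; the unexpanded molecule's own fingerprint is
    always included so the stereo maximum dominates the plain comparison."""
    opts = StereoEnumerationOptions(
        maxIsomers=int(max_isomers), onlyUnassigned=True, unique=True
    )
    out = [_bits(gen, mol)]
    if _n_undefined_centers(mol) > 0:
        seen = set()
        for iso in EnumerateStereoisomers(mol, options=opts):
            smi = Chem.MolToSmiles(iso)
            if smi in seen:
                continue
            seen.add(smi)
            out.append(_bits(gen, iso))
    # deduplicate identical bit sets, preserve order
    uniq, seen = [], set()
    for b in out:
        key = tuple(b)
        if key not in seen:
            seen.add(key)
            uniq.append(b)
    return uniq


def _parse(smiles):
    return Chem.MolFromSmiles(smiles)


def _run_reaction(rxn, mol):
    """All distinct canonical single-fragment products of rxn applied at
    every matching site of mol."""
    products = set()
    for prods in rxn.RunReactants((mol,)):
        for p in prods:
            try:
                Chem.SanitizeMol(p)
            except Exception:
                continue
            products.add(Chem.MolToSmiles(p))
    return sorted(products)


def op_fingerprints(req):
    gen = _generator(req)
    canonical, bits, n_undef, bad = [], [], [], []
    for i, smi in enumerate(req["smiles"]):
        mol = _parse(smi)
        if mol is None:
            canonical.append(None)
            bits.append(None)
            n_undef.append(None)
            bad.append(i + 1)  # 1-based for R
            continue
        canonical.append(Chem.MolToSmiles(mol))
        bits.append(_bits(gen, mol))
        n_undef.append(_n_undefined_centers(mol))
    return {"canonical": canonical, "bits": bits, "n_undef": n_undef, "bad": bad}


def op_stereo_bits(req):
    gen = _generator(req)
    max_isomers = req.get("max_isomers", 16)
    out, n_iso, bad = [], [], []
    for i, smi in enumerate(req["smiles"]):
        mol = _parse(smi)
        if mol is None:
            out.append(None)
            n_iso.append(None)
            bad.append(i + 1)
            continue
        sb = _stereo_bits(gen, mol, max_isomers)
        out.append(sb)
        n_iso.append(len(sb))
    return {"bits": out, "n_iso": n_iso, "bad": bad}


def op_n_stereoisomers(req):
    """Number of stereoisomer assignments that would be evaluated (cap applied)."""
    max_isomers = req.get("max_isomers", 16)
    out = []
    for smi in req["smiles"]:
        mol = _parse(smi)
        if mol is None:
            out.append(None)
            continue
        if _n_undefined_centers(mol) == 0:
            out.append(1)
            continue
        opts = StereoEnumerationOptions(
            maxIsomers=int(max_isomers), onlyUnassigned=True, unique=True
        )
        out.append(sum(1 for _ in EnumerateStereoisomers(mol, options=opts)))
    return {"n": out}


def op_transform(req):
    """products[i][j]: canonical product SMILES of smirks i applied to smiles j."""
    bad_smirks = []
    rxns = []
    for i, smk in enumerate(req["smirks"]):
        try:
            rxn = AllChem.ReactionFromSmarts(smk)
            if rxn is None:
                raise ValueError("unparseable")
            rxns.append(rxn)
        except Exception:
            rxns.append(None)
            bad_smirks.append(i + 1)
    mols, bad_smiles = [], []
    for j, smi in enumerate(req["smiles"]):
        mol = _parse(smi)
        if mol is None:
            bad_smiles.append(j + 1)
        mols.append(mol)
    products = []
    for rxn in rxns:
        row = []
        for mol in mols:
            if rxn is None or mol is None:
                row.append(None)
            else:
                row.append(_run_reaction(rxn, mol))
        products.append(row)
    return {"products": products, "bad_smirks": bad_smirks, "bad_smiles": bad_smiles}


def op_profile(req):
    """One-shot chemistry profile for a metabolite pool and a SMIRKS alphabet.

    Returns, per pool molecule: canonical SMILES, plain fingerprint bits,
    stereo-enumerated fingerprint bits; and per (smirks, molecule): the list
    of products, each with its stereo-enumerated bits.
    """
    gen = _generator(req)
    max_isomers = req.get("max_isomers", 16)
    ids = list(req["smiles"].keys())
    mols, canonical, bits, sbits, n_undef, bad = {}, {}, {}, {}, {}, []
    for mid in ids:
        mol = _parse(req["smiles"][mid])
        if mol is None:
            bad.append(mid)
            continue
        mols[mid] = mol
        canonical[mid] = Chem.MolToSmiles(mol)
        bits[mid] = _bits(gen, mol)
        sbits[mid] = _stereo_bits(gen, mol, max_isomers)
        n_undef[mid] = _n_undefined_centers(mol)
    if bad:
        return {"ok": False, "error": "unparseable SMILES for: " + ", ".join(bad)}
    products = []
    for smk in req.get("smirks", []):
        try:
            rxn = AllChem.ReactionFromSmarts(smk)
            if rxn is None:
                raise ValueError("unparseable")
        except Exception:
            return {"ok": False, "error": "unparseable SMIRKS: " + smk}
        per_sub = {}
        for mid in mols:
            prods = _run_reaction(rxn, mols[mid])
            entry = []
            for psmi in prods:
                pmol = _parse(psmi)
                if pmol is None:
                    continue
                entry.append({"s": psmi, "b": _stereo_bits(gen, pmol, max_isomers)})
            per_sub[mid] = entry
        products.append(per_sub)
    return {
        "canonical": canonical,
        "bits": bits,
        "sbits": sbits,
        "n_undef": n_undef,
        "products": products,
    }


OPS = {
    "fingerprints": op_fingerprints,
    "stereo_bits": op_stereo_bits,
    "n_stereoisomers": op_n_stereoisomers,
    "transform": op_transform,
    "profile": op_profile,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        resp = {"ok": False, "error": "unknown op: %r" % op}
    else:
        try:
            resp = OPS[op](req)
            if "ok" not in resp:
                resp["ok"] = True
        except Exception as exc:  # surface the message to R
            resp = {"ok": False, "error": "%s: %s" % (type(exc).__name__, exc)}
    json.dump(resp, sys.stdout)
    sys.stdout.write("\n")


if __name__ == "__main__":
    main()
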