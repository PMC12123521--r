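"""Batch chemistry backend for the molfuse R package.

Reads one JSON payload from stdin, writes one JSON payload to stdout.
Usage: python chem_backend.py <op>   with op in {canon, features, match, render}.

The helper only reports raw chemical facts (atom/bond properties, BRICS bond
lists, scaffold strings, canonical SMILES, rendered depiction PNGs); all
featurization and modelling happens on the R side. Atom indices are 0-based
here and shifted to 1-based in R.
"""
import sys
import json

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem import AllChem, BRICS
from rdkit.Chem.Draw import rdMolDraw2D
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

CHIRAL = {
    Chem.ChiralType.CHI_UNSPECIFIED: "none",
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "cw",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "ccw",
}
HYBRID = {
    Chem.HybridizationType.SP: "sp",
    Chem.HybridizationType.SP2: "sp2",
    Chem.HybridizationType.SP3: "sp3",
}
BONDTYPE = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}


def parse(smi):
    if not isinstance(smi, str) or smi == "":
        return None
    return Chem.MolFromSmiles(smi)


def mol_payload(mol):
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "symbol": a.GetSymbol(),
            "degree": a.GetDegree(),
            "charge": a.GetFormalCharge(),
            "chiral": CHIRAL.get(a.GetChiralTag(), "other"),
            "hybrid": HYBRID.get(a.GetHybridization(), "other"),
            "aromatic": bool(a.GetIsAromatic()),
        })
    bonds = []
    for b in mol.GetBonds():
        bonds.append({
            "a": b.GetBeginAtomIdx(),
            "b": b.GetEndAtomIdx(),
            "type": BONDTYPE.get(b.GetBondType(), "single"),
            "ring": bool(b.IsInRing()),
            "conj": bool(b.GetIsConjugated()),
        })
    brics = [[int(i), int(j)] for (i, j), _ in BRICS.FindBRICSBonds(mol)]
    try:
        scaffold = MurckoScaffold.MurckoScaffoldSmiles(mol=Chem.Mol(mol))
    except Exception:
        scaffold = ""
    return {
        "canonical": Chem.MolToSmiles(mol),
        "n_atoms": mol.GetNumAtoms(),
        "atoms": atoms,
        "bonds": bonds,
        "brics": brics,
        "scaffold": scaffold,
    }


def op_canon(payload):
    out = []
    for smi in payload["smiles"]:
        mol = parse(smi)
        out.append(Chem.MolToSmiles(mol) if mol is not None else None)
    return {"canonical": out}


def op_features(payload):
    perms = payload.get("perms")
    mols = []
    for k, smi in enumerate(payload["smiles"]):
        mol = parse(smi)
        if mol is None:
            mols.append(None)
            continue
        if perms is not None and perms[k] is not None:
            mol = Chem.RenumberAtoms(mol, [int(i) for i in perms[k]])
        mols.append(mol_payload(mol))
    return {"mols": mols}


def op_match(payload):
    patterns = []
    for s in payload["smarts"]:
        p = Chem.MolFromSmarts(s)
        if p is None:
            raise ValueError("invalid SMARTS pattern: %s" % s)
        patterns.append(p)
    hits = []
    for smi in payload["smiles"]:
        mol = parse(smi)
        if mol is None:
            hits.append([None] * len(patterns))
        else:
            hits.append([int(mol.HasSubstructMatch(p)) for p in patterns])
    return {"hits": hits}


def op_render(payload):
    size = int(payload.get("size", 224))
    ok = []
    for smi, path in zip(payload["smiles"], payload["files"]):
        mol = parse(smi)
        if mol is None:
            ok.append(False)
            continue
        # render from the canonical form so identical molecules give
        # bit-identical depictions regardless of the input atom order
        mol = Chem.MolFromSmiles(Chem.MolToSmiles(mol))
        AllChem.Compute2DCoords(mol)
        drawer = rdMolDraw2D.MolDraw2DCairo(size, size)
        opts = drawer.drawOptions()
        opts.addAtomIndices = False
        rdMolDraw2D.PrepareAndDrawMolecule(drawer, mol)
        drawer.FinishDrawing()
        with open(path, "wb") as fh:
            fh.write(drawer.GetDrawingText())
        ok.append(True)
    return {"ok": ok}


OPS = {"canon": op_canon, "features": op_features,
       "match": op_match, "render": op_render}


def main():
    op = sys.argv[1]
    payload = json.load(sys.stdin)
    try:
        out = OPS[op](payload)
    except Exception as exc:  # surfaced as an R error
        json.dump({"error": str(exc)}, sys.stdout)
        return
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
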