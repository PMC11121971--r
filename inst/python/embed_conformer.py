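"""Seeded 3D conformer embedding for the MIF engine.

Reads a TSV of (id, smiles) records, embeds one low-energy conformer per
molecule with RDKit ETKDGv3 (distance geometry; deterministic for a fixed
seed), relaxes it with MMFF94 (UFF fallback), assigns Gasteiger partial
charges and hydrogen-bond role flags, and writes a JSON array of atom tables.

Usage: python embed_conformer.py <in.tsv> <out.json> <seed> [max_retries]
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed_one(smiles, seed, max_retries):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"status": "parse_error"}
    mol = Chem.AddHs(mol)
    conf_id = -1
    used_seed = None
    for k in range(max_retries + 1):
        params = AllChem.ETKDGv3()
        params.randomSeed = seed + k
        conf_id = AllChem.EmbedMolecule(mol, params)
        if conf_id >= 0:
            used_seed = seed + k
            break
    if conf_id < 0:
        return {"status": "embed_error", "retries": max_retries}
    try:
        AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
    except Exception:
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    AllChem.ComputeGasteigerCharges(mol)
    conf = mol.GetConformer()
    elements, xyz, charges, acceptor, polar_h = [], [], [], [], []
    for atom in mol.GetAtoms():
        pos = conf.GetAtomPosition(atom.GetIdx())
        elements.append(atom.GetSymbol())
        xyz.append([round(pos.x, 4), round(pos.y, 4), round(pos.z, 4)])
        q = atom.GetDoubleProp("_GasteigerCharge")
        charges.append(round(q if q == q else 0.0, 4))  # NaN guard
        acceptor.append(1 if atom.GetAtomicNum() in (7, 8) else 0)
        is_polar_h = atom.GetAtomicNum() == 1 and any(
            nb.GetAtomicNum() in (7, 8) for nb in atom.GetNeighbors()
        )
        polar_h.append(1 if is_polar_h else 0)
    return {
        "status": "ok",
        "seed": used_seed,
        "element": elements,
        "xyz": xyz,
        "charge": charges,
        "acceptor": acceptor,
        "polar_h": polar_h,
    }


def main(argv):
    tsv_in, json_out, seed = argv[1], argv[2], int(argv[3])
    max_retries = int(argv[4]) if len(argv) > 4 else 5
    records = []
    with open(tsv_in) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            mol_id, smiles = line.split("\t", 1)
            res = embed_one(smiles, seed, max_retries)
            res["id"] = mol_id
            records.append(res)
    with open(json_out, "w") as fh:
        json.dump(records, fh)


if __name__ == "__main__":
    main(sys.argv)
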