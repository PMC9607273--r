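#!/usr/bin/env python
"""Batch 3D conformer embedding for the pon1qsar R package.

Reads a tab-separated file of (compound_id, smiles) pairs, embeds one
conformer per compound with RDKit's ETKDG distance-geometry algorithm at a
fixed random seed, relaxes it with the MMFF94 force field (UFF fallback for
molecules outside MMFF coverage), and writes a multi-record V2000 SDF whose
record titles are the compound ids. Fully deterministic given the seed.

Usage: embed_conformers.py <input.tsv> <seed> <output.sdf>

On an unparseable SMILES or a failed embedding the offending compound id is
printed to stderr and the exit status is 1.
"""

import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def embed(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(mol, params) != 0:
        return None
    try:
        status = AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
        if status == -1:  # MMFF parameters unavailable for this molecule
            AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    except Exception:
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    return mol


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: embed_conformers.py <input.tsv> <seed> <out.sdf>\n")
        return 2
    in_path, seed, out_path = argv[1], int(argv[2]), argv[3]
    writer = Chem.SDWriter(out_path)
    writer.SetKekulize(True)
    failures = []
    with open(in_path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smiles = line.split("\t", 1)
            mol = embed(smiles, seed)
            if mol is None:
                failures.append(cid)
                continue
            mol.SetProp("_Name", cid)
            writer.write(mol)
    writer.close()
    if failures:
        sys.stderr.write("embedding failed for: " + ", ".join(failures) + "\n")
        return 1
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
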