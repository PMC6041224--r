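#!/usr/bin/env python
"""Batched RDKit worker for the molcvae R package.

Reads SMILES strings from stdin (one per line) and writes one TSV record per
input line to stdout:

    valid  canonical  mw  logp  hbd  hba  tpsa

valid is 0/1; for invalid inputs the remaining fields are "NA".  mw is the
exact (monoisotopic) mass in Da, logp the Wildman-Crippen octanol-water
partition coefficient, hbd/hba Lipinski-style donor/acceptor counts, tpsa the
Ertl topological polar surface area in A^2.  Input lines are taken verbatim
(no comment handling here); an empty line is an invalid molecule.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, Lipinski

RDLogger.DisableLog("rdApp.*")


def main():
    out = sys.stdout
    for line in sys.stdin:
        smi = line.rstrip("\n")
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            out.write("0\tNA\tNA\tNA\tNA\tNA\tNA\n")
            continue
        out.write(
            "1\t%s\t%.6f\t%.6f\t%d\t%d\t%.6f\n"
            % (
                Chem.MolToSmiles(mol),
                Descriptors.ExactMolWt(mol),
                Crippen.MolLogP(mol),
                Lipinski.NumHDonors(mol),
                Lipinski.NumHAcceptors(mol),
                Descriptors.TPSA(mol),
            )
        )


if __name__ == "__main__":
    main()
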