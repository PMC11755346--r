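"""Hashed Morgan (ECFP) fingerprints for a batch of SMILES.

Reads a TSV of (id, smiles) from the path in argv[1] and writes, to the path
in argv[2], one line per input: "<id>\tOK\t<comma separated on-bit indices>"
or "<id>\tERR\t<message>". Radius and bit count come from argv[3]/argv[4].
Kept deliberately free of any non-rdkit dependency.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main() -> None:
    src, dst, radius, n_bits = sys.argv[1], sys.argv[2], int(sys.argv[3]), int(sys.argv[4])
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
    out = []
    with open(src, encoding="utf-8") as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                out.append(f"{ident}\tERR\tunparseable SMILES: {smiles}")
                continue
            bits = ",".join(str(i) for i in gen.GetFingerprint(mol).GetOnBits())
            out.append(f"{ident}\tOK\t{bits}")
    with open(dst, "w", encoding="utf-8") as fh:
        fh.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main()
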