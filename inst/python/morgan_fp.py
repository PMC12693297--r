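"""Batch Morgan fingerprint helper.

Reads one SMILES per line on stdin; writes one tab-separated line per input:
    OK<TAB>canonical_smiles<TAB>comma-separated 0-based on-bit indices
or  ERR<TAB><original smiles>
Usage: python morgan_fp.py <radius> <nbits> <chiral:0|1>
"""
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import rdFingerprintGenerator

rdBase.DisableLog("rdApp.*")


def main() -> None:
    radius = int(sys.argv[1])
    nbits = int(sys.argv[2])
    chiral = sys.argv[3] == "1"
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=radius, fpSize=nbits, includeChirality=chiral
    )
    out = sys.stdout
    for line in sys.stdin:
        smi = line.rstrip("\n")
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.write("ERR\t%s\n" % smi)
            continue
        fp = gen.GetFingerprint(mol)
        bits = ",".join(str(b) for b in fp.GetOnBits())
        out.write("OK\t%s\t%s\n" % (Chem.MolToSmiles(mol), bits))


if __name__ == "__main__":
    main()
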