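Worked-example fixtures for the homolog-identity acceptance check.

Each file pairs one deposited amplicon protein with its named
characterised reductive dehalogenase, two protein records per FASTA
(query first, reference second):

  KF138765__VcrA.fasta   deposited amplicon vs the vinyl chloride
                         reductase VcrA of Dehalococcoides mccartyi VS
  KF138603__BvcA.fasta   deposited amplicon vs the vinyl chloride
                         reductase BvcA of D. mccartyi BAV1
  KF138991__TceA.fasta   deposited amplicon vs the trichloroethene
                         reductase TceA of D. mccartyi 195

The records are public database entries and must be fetched over the
network (translate the deposited nucleotide accession, pair it with the
reference protein).  They are NOT redistributed here, so the directory
ships empty and the corresponding acceptance test reports a failure in
offline environments.
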