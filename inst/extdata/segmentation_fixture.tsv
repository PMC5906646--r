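Smith et al. <bibr:B1> reported strong binding. We confirm this result.	Smith et al. <bibr:B1> reported strong binding.	We confirm this result.
H. pylori infects the gastric mucosa. It is remarkably common worldwide.	H. pylori infects the gastric mucosa.	It is remarkably common worldwide.
The dose was ca. 5 mg per kilogram. Results follow below.	The dose was ca. 5 mg per kilogram.	Results follow below.
E. coli cultures grew overnight, e.g. in rich medium. Colonies were counted.	E. coli cultures grew overnight, e.g. in rich medium.	Colonies were counted.
S. cerevisiae divides by budding. D. melanogaster develops in stages.	S. cerevisiae divides by budding.	D. melanogaster develops in stages.
Binding was saturable.<bibr:B2> Affinity was high.<bibr:B3> Kinetics were slow.	Binding was saturable.<bibr:B2>	Affinity was high.<bibr:B3>	Kinetics were slow.
The effect was reported earlier.[<bibr:B4>] Replication failed twice.	The effect was reported earlier.[<bibr:B4>]	Replication failed twice.
See Fig. 2 for the alignment. The motif is conserved.	See Fig. 2 for the alignment.	The motif is conserved.
Values were normalized, i.e. scaled to unit variance. Outliers were removed.	Values were normalized, i.e. scaled to unit variance.	Outliers were removed.
Dr. Jones described the assay protocol. It requires two buffers.	Dr. Jones described the assay protocol.	It requires two buffers.
Expression rose threefold vs. untreated controls. The change was significant.	Expression rose threefold vs. untreated controls.	The change was significant.
The sample contained approx. 200 cells. Imaging took ca. 3 hours.	The sample contained approx. 200 cells.	Imaging took ca. 3 hours.
Turnover is rapid <bibr:B5> in vivo. Half-life is short, cf. earlier work.	Turnover is rapid <bibr:B5> in vivo.	Half-life is short, cf. earlier work.
As shown in <nbib:F1> the signal peaks early. Decay follows within minutes.	As shown in <nbib:F1> the signal peaks early.	Decay follows within minutes.
Both effects were described by Lee et al. <bibr:B6><bibr:B7> last year. Neither was replicated. Controls behaved as expected.	Both effects were described by Lee et al. <bibr:B6><bibr:B7> last year.	Neither was replicated.	Controls behaved as expected.
X. laevis oocytes expressed the channel. Currents were recorded. The conductance matched earlier reports.<bibr:B8>	X. laevis oocytes expressed the channel.	Currents were recorded.	The conductance matched earlier reports.<bibr:B8>
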