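command=predict
package_version=0.1.0
timestamp=2026-09-29T08:46:19+0000
checkpoint=/tmp/RtmpJMmYgU/file14dd17ab065c
fasta=x
pairs=y
out=z
score_mode=mid
theta=NA
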