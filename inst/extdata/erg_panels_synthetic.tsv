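gene	chrom	pos
Esr1	chr1	41200406
Esr1	chr1	41200439
Esr1	chr1	41200484
Esr1	chr1	41200526
Esr1	chr1	41200579
Esr1	chr1	41200595
Esr1	chr1	41200624
Esr1	chr1	41200664
Esr1	chr1	41200732
Esr1	chr1	41200754
Esr1	chr1	41200824
Esr1	chr1	41200841
Esr1	chr1	41200879
Esr1	chr1	41200933
Ar	chrX	68534536
Ar	chrX	68534597
Ar	chrX	68534619
Ar	chrX	68534659
Ar	chrX	68534685
Ar	chrX	68534750
Ar	chrX	68534784
Ar	chrX	68534838
Ar	chrX	68534849
Ar	chrX	68534947
Ar	chrX	68534976
Ar	chrX	68534996
Ar	chrX	68535026
Ar	chrX	68535062
Ar	chrX	68535097
Ar	chrX	68535115
Ar	chrX	68535140
Pgr	chr8	54120152
Pgr	chr8	54120192
Pgr	chr8	54120229
Pgr	chr8	54120245
Pgr	chr8	54120295
Pgr	chr8	54120347
Pgr	chr8	54120417
Pgr	chr8	54120474
Pgr	chr8	54120496
Pgr	chr8	54120527
Pgr	chr8	54120555
Pgr	chr8	54120605
Pgr	chr8	54120622
Pgr	chr8	54120681
Pgr	chr8	54120748
Pgr	chr8	54120786
Pgr	chr8	54120841
Pgr	chr8	54120908
Pgr	chr8	54120944
Cxcl12	chr4	78455222
Cxcl12	chr4	78455281
Cxcl12	chr4	78455342
Cxcl12	chr4	78455397
Cxcl12	chr4	78455442
Cxcl12	chr4	78455490
Cxcl12	chr4	78455536
Cxcl12	chr4	78455562
Cxcl12	chr4	78455597
Cxcl12	chr4	78455619
Cxcl12	chr4	78455657
Cxcl12	chr4	78455681
Cxcl12	chr4	78455741
Cd9	chr4	157901854
Cd9	chr4	157901916
Cd9	chr4	157901980
Cd9	chr4	157902017
Cd9	chr4	157902036
Cd9	chr4	157902082
Cd9	chr4	157902134
Cd9	chr4	157902151
Cd9	chr4	157902218
Cd9	chr4	157902273
Bcl11b	chr6	133478480
Bcl11b	chr6	133478549
Bcl11b	chr6	133478571
Bcl11b	chr6	133478613
Bcl11b	chr6	133478643
Bcl11b	chr6	133478707
Bcl11b	chr6	133478739
Bcl11b	chr6	133478793
Bcl11b	chr6	133478836
Bcl11b	chr6	133478888
Mpped2	chr3	96122624
Mpped2	chr3	96122683
Mpped2	chr3	96122727
Mpped2	chr3	96122797
Mpped2	chr3	96122850
Mpped2	chr3	96122920
Mpped2	chr3	96122956
Mpped2	chr3	96123014
Mpped2	chr3	96123034
Mpped2	chr3	96123052
Tgm2	chr3	152377962
Tgm2	chr3	152378025
Tgm2	chr3	152378082
Tgm2	chr3	152378109
Tgm2	chr3	152378167
Tgm2	chr3	152378236
Tgm2	chr3	152378305
Tgm2	chr3	152378337
Tgm2	chr3	152378384
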