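"ID","TIME","EVID","AMT","DV","MDV","SS","II","ALB","BSA","TAC"
"S001",324,1,0.25,,1,1,12,3.57677309643688,1.82724292975246,2.43104136583987
"S001",336,0,,1.60728544152238,0,0,,3.57677309643688,1.82724292975246,2.43104136583987
"S001",408,1,0.25,,1,1,12,3.57677309643688,1.82724292975246,2.43104136583987
"S001",420,0,,1.53277322473957,0,0,,3.57677309643688,1.82724292975246,2.43104136583987
"S001",492,1,0.25,,1,1,12,3.57677309643688,1.82724292975246,2.43104136583987
"S001",504,0,,1.1474889891595,0,0,,3.57677309643688,1.82724292975246,2.43104136583987
"S002",324,1,1,,1,1,12,3.7268833173909,1.85952807747517,2.20012200635607
"S002",336,0,,0.0330263692845595,0,0,,3.7268833173909,1.85952807747517,2.20012200635607
"S002",408,1,1,,1,1,12,3.7268833173909,1.85952807747517,2.20012200635607
"S002",420,0,,2.01684004582266,0,0,,3.7268833173909,1.85952807747517,2.20012200635607
"S002",492,1,1,,1,1,12,3.7268833173909,1.85952807747517,2.20012200635607
"S002",504,0,,1.50289732411301,0,0,,3.7268833173909,1.85952807747517,2.20012200635607
"S003",324,1,0.75,,1,1,12,3.98182166209245,1.74146414292846,7.96658066815012
"S003",336,0,,2.64123913742854,0,0,,3.98182166209245,1.74146414292846,7.96658066815012
"S003",408,1,0.75,,1,1,12,3.98182166209245,1.74146414292846,7.96658066815012
"S003",420,0,,0.79087820111376,0,0,,3.98182166209245,1.74146414292846,7.96658066815012
"S003",492,1,0.75,,1,1,12,3.98182166209245,1.74146414292846,7.96658066815012
"S003",504,0,,2.1876331870329,0,0,,3.98182166209245,1.74146414292846,7.96658066815012
"S004",324,1,1.5,,1,1,12,4.55489962972769,1.73295077829207,3.94077392701942
"S004",336,0,,11.7370118560123,0,0,,4.55489962972769,1.73295077829207,3.94077392701942
"S004",408,1,1.5,,1,1,12,4.55489962972769,1.73295077829207,3.94077392701942
"S004",420,0,,16.2423837722588,0,0,,4.55489962972769,1.73295077829207,3.94077392701942
"S004",492,1,1.5,,1,1,12,4.55489962972769,1.73295077829207,3.94077392701942
"S004",504,0,,9.24314094861261,0,0,,4.55489962972769,1.73295077829207,3.94077392701942
"S005",324,1,2.5,,1,1,12,3.4721856893479,1.54600499970816,9.90488480296495
"S005",336,0,,26.587625992301,0,0,,3.4721856893479,1.54600499970816,9.90488480296495
"S005",408,1,2.5,,1,1,12,3.4721856893479,1.54600499970816,9.90488480296495
"S005",420,0,,21.7382119122811,0,0,,3.4721856893479,1.54600499970816,9.90488480296495
"S005",492,1,2.5,,1,1,12,3.4721856893479,1.54600499970816,9.90488480296495
"S005",504,0,,7.20288133161916,0,0,,3.4721856893479,1.54600499970816,9.90488480296495
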