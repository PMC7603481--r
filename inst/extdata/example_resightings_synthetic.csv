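individual_id,year,colony,patch_id
IND0002,2002,SIM,P00002
IND0003,2002,SIM,P00002
IND0004,2002,SIM,P00001
IND0008,2002,SIM,P00001
IND0011,2002,SIM,P00003
IND0014,2002,SIM,P00003
IND0016,2002,SIM,P00003
IND0018,2002,SIM,P00002
IND0020,2002,SIM,P00001
IND0025,2002,SIM,P00003
IND0029,2002,SIM,P00005
IND0031,2002,SIM,P00003
IND0033,2002,SIM,P00003
IND0034,2002,SIM,P00001
IND0035,2002,SIM,P00003
IND0037,2002,SIM,P00002
IND0039,2002,SIM,P00003
IND0002,2003,SIM,P00013
IND0004,2003,SIM,P00008
IND0006,2003,SIM,P00014
IND0009,2003,SIM,P00013
IND0011,2003,SIM,P00011
IND0012,2003,SIM,P00014
IND0018,2003,SIM,P00013
IND0024,2003,SIM,P00010
IND0026,2003,SIM,P00010
IND0028,2003,SIM,P00013
IND0032,2003,SIM,P00013
IND0034,2003,SIM,P00008
IND0001,2004,SIM,P00015
IND0002,2004,SIM,P00015
IND0006,2004,SIM,P00014
IND0009,2004,SIM,P00015
IND0013,2004,SIM,P00012
IND0018,2004,SIM,P00015
IND0019,2004,SIM,P00014
IND0024,2004,SIM,P00012
IND0028,2004,SIM,P00015
IND0034,2004,SIM,P00016
IND0037,2004,SIM,P00015
IND0039,2004,SIM,P00016
IND0001,2005,SIM,P00017
IND0004,2005,SIM,P00017
IND0006,2005,SIM,P00022
IND0010,2005,SIM,P00022
IND0016,2005,SIM,P00022
IND0018,2005,SIM,P00020
IND0020,2005,SIM,P00017
IND0021,2005,SIM,P00019
IND0022,2005,SIM,P00020
IND0024,2005,SIM,P00019
IND0025,2005,SIM,P00021
IND0030,2005,SIM,P00022
IND0032,2005,SIM,P00020
IND0033,2005,SIM,P00019
IND0038,2005,SIM,P00017
IND0039,2005,SIM,P00017
IND0001,2006,SIM,P00030
IND0003,2006,SIM,P00029
IND0006,2006,SIM,P00021
IND0008,2006,SIM,P00030
IND0010,2006,SIM,P00021
IND0011,2006,SIM,P00029
IND0013,2006,SIM,P00029
IND0019,2006,SIM,P00021
IND0020,2006,SIM,P00030
IND0022,2006,SIM,P00029
IND0024,2006,SIM,P00029
IND0027,2006,SIM,P00021
IND0032,2006,SIM,P00029
IND0034,2006,SIM,P00030
IND0036,2006,SIM,P00030
IND0037,2006,SIM,P00029
IND0040,2006,SIM,P00030
IND0002,2007,SIM,P00029
IND0004,2007,SIM,P00027
IND0006,2007,SIM,P00034
IND0011,2007,SIM,P00036
IND0016,2007,SIM,P00034
IND0018,2007,SIM,P00029
IND0023,2007,SIM,P00036
IND0025,2007,SIM,P00029
IND0030,2007,SIM,P00034
IND0039,2007,SIM,P00035
IND0002,2008,SIM,P00039
IND0006,2008,SIM,P00034
IND0009,2008,SIM,P00039
IND0010,2008,SIM,P00034
IND0017,2008,SIM,P00030
IND0020,2008,SIM,P00030
IND0022,2008,SIM,P00039
IND0024,2008,SIM,P00034
IND0025,2008,SIM,P00034
IND0027,2008,SIM,P00034
IND0030,2008,SIM,P00034
IND0034,2008,SIM,P00030
IND0036,2008,SIM,P00030
IND0039,2008,SIM,P00030
IND0002,2009,SIM,P00027
IND0003,2009,SIM,P00027
IND0004,2009,SIM,P00041
IND0006,2009,SIM,P00039
IND0009,2009,SIM,P00027
IND0010,2009,SIM,P00039
IND0011,2009,SIM,P00041
IND0020,2009,SIM,P00041
IND0024,2009,SIM,P00041
IND0025,2009,SIM,P00027
IND0027,2009,SIM,P00039
IND0030,2009,SIM,P00039
IND0040,2009,SIM,P00041
IND0004,2010,SIM,P00049
IND0007,2010,SIM,P00050
IND0009,2010,SIM,P00050
IND0011,2010,SIM,P00047
IND0017,2010,SIM,P00049
IND0020,2010,SIM,P00045
IND0023,2010,SIM,P00047
IND0024,2010,SIM,P00047
IND0030,2010,SIM,P00050
IND0032,2010,SIM,P00050
IND0040,2010,SIM,P00049
IND0009,2011,SIM,P00052
IND0010,2011,SIM,P00047
IND0017,2011,SIM,P00045
IND0018,2011,SIM,P00052
IND0020,2011,SIM,P00051
IND0022,2011,SIM,P00052
IND0023,2011,SIM,P00051
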